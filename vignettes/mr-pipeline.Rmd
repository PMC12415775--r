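---
title: "Methods: two-sample MR, mediation and biomarker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation and biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbemr)
```

## The causal model

Two-sample MR estimates the effect of an exposure (here: the relative
abundance of a gut-microbiome taxon, or a blood metabolite or
immune-cell trait) on a binary disease outcome from two independent
GWAS. For instrument $j$, let $\gamma_j$ be its effect on the exposure
and $\Gamma_j$ its effect on the outcome (log-odds scale). Under the
instrumental-variable assumptions (relevance, independence from
confounders, no path to the outcome other than through the exposure),
$\Gamma_j = \beta\,\gamma_j$, and each variant provides a Wald ratio
estimate $r_j = \hat\Gamma_j/\hat\gamma_j$ with first-order standard
error $se(r_j) = se(\hat\Gamma_j)/|\hat\gamma_j|$. The first-order
form ignores exposure-side noise; it is the standard default, and the
instrument-strength filter (F ≥ 10, with realistic instrument sets far
above that after the $p<10^{-5}$ screen) keeps the ignored term small.

Violations of the third assumption — horizontal pleiotropy — are the
central threat. The estimator suite spans the standard bias-robustness
trade-off:

* **IVW**: $\hat\beta = \sum w_j r_j / \sum w_j$, $w_j = 1/se(r_j)^2$.
  Efficient, but biased by any net pleiotropy. The default is the
  multiplicative random-effects variant, which inflates the
  fixed-effect standard error by $\max(1, \sqrt{Q/(J-1)})$ — it never
  deflates, so under homogeneity it coincides with the fixed-effect
  form and under the null it is, if anything, conservative. The
  fixed-effect variant is what the calibration checks exercise, since
  its 5% size under a clean null is the textbook property; both are
  available via `mr_ivw(model =)`.
* **MR-Egger**: weighted regression of $\hat\Gamma_j$ on
  $\hat\gamma_j$ *with* an intercept, after re-signing each instrument
  so $\hat\gamma_j \ge 0$. Under InSIDE (instrument strength
  independent of direct effects) the slope is consistent despite
  directional pleiotropy, and the intercept estimates its mean.
  Standard errors are inflated by $\max(1,\sqrt{RSS/(J-2)})$ and
  referred to $t_{J-2}$.
* **Weighted median**: the inverse-variance-weighted median of the
  ratios, interpolated at centered cumulative weight 0.5
  ($p_j = (\sum_{k\le j} w_k - w_j/2)/\sum w$; the centered form is
  what makes equal weights over ratios $\{1,2,3\}$ return exactly 2).
  Consistent while valid instruments hold a majority of the weight.
* **Simple and weighted modes**: the mode of a Gaussian-kernel density
  over the ratios, bandwidth $\varphi \cdot 0.9\min(sd,
  IQR/1.349)J^{-1/5}$ with $\varphi = 1$ (when the IQR is zero but the
  spread is not, the sd alone sets the bandwidth; identical ratios are
  returned directly). Consistent when the largest group of
  instruments sharing a ratio is valid.

Median and mode standard errors come from a seeded parametric
bootstrap (default 1000 replicates) that redraws both effect arrays
from their sampling distributions. A finding is classified causal
(`classify_causal_signal()`) when IVW has $p < 0.05$ and every
reported method agrees in direction — a deliberately stringent rule
that trades power for robustness.

## Instrument selection and harmonization

Selection keeps variants with exposure $p < 10^{-5}$ (the relaxed
threshold used for microbiome GWAS, where genome-wide significant hits
are scarce) and $F = (\beta/se)^2 \ge 10$. Clumping is greedy: the
smallest-p unclaimed variant becomes an index and claims all variants
on the same chromosome with $r^2 \ge 0.01$ within 10,000 kb
(center-to-center, strictly inside the window; ties in p broken by
chromosome, position, identifier). LD comes from an explicit pairwise
lookup supplied by the caller or by the generators — the package
downloads nothing, and real-data use requires reference-panel r²
values.

Harmonization aligns outcome records onto the exposure's effect
allele: swapped alleles negate the outcome effect and complement the
frequency; strand complements (A↔T, C↔G) are resolved first when the
pair is unambiguous. Palindromic variants cannot be strand-resolved
from alleles; they are oriented by frequency agreement when both
frequencies are available and outside the ambiguity band (default:
within [0.42, 0.58] is dropped — the conventional default in
two-sample MR tooling), and dropped otherwise. Every decision is
recorded per variant (`kept`, `flipped`, `dropped_*`), and the whole
procedure is idempotent and invariant to a consistent re-orientation
of the outcome file.

## Sensitivity suite

Cochran's Q uses the fixed-effect IVW center (the standard
definition) regardless of which IVW variant is reported. The Egger
intercept test shares its computation with `mr_egger()` — the two
report bit-identical triples. MR-PRESSO follows the published
algorithm's structure: the observed residual sum of squares
$\sum_j w_j(\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2$ (with
leave-one-out IVW slopes) is compared with `n_sim` parametric
simulations drawn under the leave-one-out fitted model; per-variant
contributions give outlier p-values, Bonferroni-flagged at 0.05; the
corrected estimate is IVW on the unflagged subset; and the distortion
test compares the observed shift two-sidedly against shifts from
removing equally many random variants. Monte-Carlo p-values are
floored at $1/(n_{sim}+1)$ so they are never zero.

## Mediation

Two-step MR: $\beta_1$ (exposure→mediator) and $\beta_2$
(mediator→outcome) are univariable IVW estimates — the product method,
not multivariable MR. The indirect effect is $\beta_1\beta_2$ with
first-order delta-method SE
$\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$ (the exact product SD
adds an $se_1^2 se_2^2$ term, a few percent at realistic
signal-to-noise), and the proportion mediated is
$\beta_1\beta_2/\beta_{total}$ with an interval obtained by
propagating the indirect-effect CI over the total effect treated as
fixed — a simplification that understates uncertainty in the
proportion when the total effect is itself noisy, flagged here as a
known limitation. `mediation_screen()` retains mediators whose two
steps are both classified significant-and-consistent at $p<0.05$ and
ranks them by $|proportion|$; output flags, rather than resolves, the
case where indirect and total effects disagree in sign.

Reverse MR deserves a caution the package makes visible: when the
outcome GWAS is as well powered as the exposure GWAS, the exposure
instruments' *induced* outcome associations can pass the reverse
instrument screen, and reverse MR then estimates $1/\beta$ rather
than a genuine reverse effect. The bidirectional tests therefore use a
weaker outcome GWAS (as is realistic for a rare binary outcome) — the
setting in which reverse-null calibration is meaningful.

## The synthetic-data generators

Summary statistics are simulated directly — two-sample MR consumes
only summary data, and this keeps calibration runs in seconds. Per
variant: frequency uniform on [0.05, 0.5]; standard errors
$1/\sqrt{2\,maf(1-maf)\,n}$; true instrument effects
$\gamma_j \sim N(0, 0.05^2)$ conditioned (for a configurable fraction,
default all) to exceed `min_f` in true F. The default `min_f` is
$\Phi^{-1}(1-5\times10^{-6})^2 \approx 19.5$, not 10: instruments in a
real analysis have passed the $p<10^{-5}$ screen, which implies
observed $F \gtrsim 19.5$, and calibration against unrealistically
weak instruments would mostly measure weak-instrument noise.

Pleiotropy has two frames, both available because they answer
different questions. In the default frame ($\Gamma_j = \beta\gamma_j
+ \alpha_j$, reported-allele frame) a constant $\alpha$ contaminates
the Wald ratios symmetrically (since $\gamma_j$ is symmetric around
zero) — the right setting for studying the weighted median's
robustness to a minority of invalid instruments. With
`pleio_oriented = TRUE`, $\alpha_j$ acts relative to the
exposure-increasing allele ($\Gamma_j = \beta\gamma_j +
\mathrm{sign}(\gamma_j)\alpha_j$); only this form survives MR-Egger's
re-orientation as directional pleiotropy, so it is the setting in
which a planted mean intercept of 0.1 is recoverable. An
`inside_cor` option correlates $\alpha_j$ with instrument strength to
stress the InSIDE assumption. LD enters only through the returned
lookup (block-diagonal, $r^2 = \rho^2$ within blocks); observed
effects are drawn independently, so the LD structure exercises the
clumping logic, not correlated sampling noise.

The cohort generator draws zero-inflated log-normal relative
abundances per group (default: five genera at means near
$10^{-3}$–$10^{-2}$, log-sd 0.9, 10% zeros — the sparse, skewed shape
genus-level metagenomic abundances have) for 28 healthy controls, 20
cognitively normal patients and 27 demented patients. MMSE scores are
drawn around group means (29.2 ± 0.9, 28.5 ± 1.2, 19.3 ± 4.1 —
controls at ceiling, dementia far below) and blended with the
standardized abundance of a designated taxon; the blend weight is
solved against the realized group draw so the *overall*
abundance–MMSE correlation targets `cor_r` (default −0.316). A naive
fixed-weight blend overshoots, because the between-group structure
(abundance and MMSE both differ by group) adds to the within-group
blend. The achieved correlation is recorded in the returned truth.

What the generators do **not** emulate: real allele-frequency spectra
and case-control imbalance beyond a configurable n; correlated
sampling noise under LD; compositionality constraints beyond the
sum-to-at-most-one cap; taxon-taxon correlation; covariate structure
(age, sex, education) in the cohort. Passing tests demonstrate that
the algorithms are correct and calibrated under the stated model —
not that any particular real-data finding is true.

## The biomarker stage

Group differences use the tie-corrected Kruskal-Wallis test with
effect size $\eta^2_H = (H - k + 1)/(n - k)$ and both Bonferroni and
Benjamini-Hochberg adjustment (different tables conventionally report
either). Power is simulation-based — the test's power against the
moment-fitted zero-inflated log-normal group parameters at the
observed group sizes — and labelled as such, since no closed form
covers this family.

The ROC curve sweeps all observed thresholds; AUC is the Mann-Whitney
concordance probability with ties counted half (identical to the
trapezoid area), and its CI is a seeded stratified bootstrap (default
2000 resamples) — preferred over closed forms because n = 75 with
zero-inflated abundances produces heavy ties. The cutoff maximizes
Youden's J, taking the lowest cutoff on ties; the marker's risk
direction is auto-detected from the AUC side and recorded, so
protective markers classify with ≤. Marker combination fits a binary
logistic model by IRLS implemented in-module (≤ 50 iterations,
log-likelihood tolerance $10^{-8}$; rank-deficient designs drop
aliased columns, so duplicated markers change nothing; complete
separation is detected and reported, with the last iterate's score
still usable for ranking) and evaluates the linear predictor as a
single score.

## Numerical conventions and problem sizes

Bootstrap and simulation counts default to 1000 (estimator SEs,
MR-PRESSO) and 2000 (AUC CI); every stochastic routine takes an
explicit seed, restores the caller's RNG state, and is bit-reproducible.
CI multipliers are fixed at 1.96. A p-value of exactly zero on input
is clamped to the smallest positive double. Zero bandwidth in the
mode estimator (all ratios identical) returns that ratio. Constant
scores yield a degenerate diagnostic report with a warning rather
than an error.

The package's statistical checks run at: 2000 replicates for null
calibration of IVW and Cochran's Q (3-binomial-SE band around 5%);
500 replicates at J = 100, n = 100k for IVW recovery, weighted-median
contamination robustness, Egger-intercept recovery and mediation
recovery; 200 replicates at J = 30 with 1000 simulations each for
MR-PRESSO detection and correction rates; 250 replicates for the
uniformity of the MR-PRESSO global p. These sizes put Monte-Carlo
error comfortably inside each assertion band while keeping the whole
suite under a minute of simulation time.
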