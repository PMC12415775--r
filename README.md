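# microbemr

Two-sample Mendelian randomization (MR), mediation analysis and
case-control biomarker evaluation for gut-microbiome–disease studies,
in R.

## The problem

Observational associations between gut microbiome composition and
neurodegenerative outcomes such as Parkinson's disease dementia are
easily confounded (diet, medication, disease severity) and may run in
either direction. Two-sample MR sidesteps both problems by using
genetic variants as instruments: a variant that raises the abundance of
a taxon is randomized at conception, so its association with the
disease reflects the taxon's causal effect — provided the variant
affects the disease only through the taxon. This package implements
the full desk pipeline a study of this kind needs:

1. **Instrument selection** — variants associated with the exposure at
   `p < 1e-5`, pruned to approximate independence by greedy LD clumping
   (`r² < 0.01` within a 10,000 kb window), with weak instruments
   (`F = (β/se)² < 10`) removed.
2. **Harmonization** — the outcome summary statistics are aligned onto
   the exposure's effect allele, flipping swapped alleles, resolving
   strand complements, and dropping palindromic (A/T, G/C) variants
   whose allele frequency is too close to 0.5 to orient.
3. **Estimation** — five estimators over the per-variant Wald ratios
   `r_j = Γ_j / γ_j` (outcome effect over exposure effect):
   inverse-variance weighted (IVW, the primary method),
   `β̂ = Σ w_j r_j / Σ w_j` with `w_j = 1/se(r_j)²`; MR-Egger
   (weighted regression with an intercept that absorbs directional
   pleiotropy); the weighted median (consistent when valid instruments
   carry >50% of the weight); and the simple and weighted modes.
   Results are reported as odds ratios with 95% CIs; a finding is
   called causal when IVW has `p < 0.05` and all methods agree in
   direction.
4. **Sensitivity** — Cochran's Q heterogeneity test, the MR-Egger
   intercept test, MR-PRESSO (simulation-based residual-sum-of-squares
   global test, per-variant outlier flagging, outlier-corrected
   estimate and distortion test) and leave-one-out influence analysis.
5. **Bidirectional MR and two-step mediation** — the reverse direction
   is tested with its own instruments; candidate mediators (blood
   metabolites, immune-cell traits) are screened by the product method:
   indirect effect `β₁β₂`, delta-method SE, and proportion mediated
   `β₁β₂ / β_total`.
6. **Case-control biomarker evaluation** — Kruskal-Wallis tests across
   HC / PD-NC / PDD groups with η²_H effect sizes, Bonferroni and FDR
   adjustment and simulation-based power; ROC/AUC with a bootstrap CI,
   Youden-J optimal cutoff, confusion-matrix summaries, logistic
   combination of markers, and Pearson correlation of abundance with
   MMSE scores.

Because real microbiome and disease GWAS catalogs are external
resources, the package ships synthetic-data generators with known
ground truth (`simulate_summary_stats()`, `simulate_mediation_triplet()`,
`simulate_cohort()`) that emulate the study's data under a linear
causal model with configurable pleiotropy, LD-block structure, and a
zero-inflated log-normal three-group abundance cohort.

## Worked example

```r
library(microbemr)

# a synthetic exposure-outcome GWAS pair with a true effect of 0.35
sim <- simulate_summary_stats(simulation_truth(
  beta_causal = 0.35, j_snps = 40, n_exp = 50000, n_out = 50000,
  seed = 42))
report <- run_mr(sim$exposure, sim$outcome, mr_config(), seed = 42)
print(report)
#> MR report: synthetic_exposure -> synthetic_outcome [ok]
#>   classification: significant_consistent, 34 instrument(s)
#>            method n_snp      beta         se         pval      or_   ci_low  ci_high
#> 1             ivw    34 0.3455341 0.01774106 1.737001e-84 1.412744 1.364464 1.462733
#> 2        mr_egger    34 0.3788724 0.04612015 2.201332e-09 1.460637 1.334394 1.598823
#> 3 weighted_median    34 0.3449678 0.02805944 9.734285e-35 1.411944 1.336389 1.491771
#> 4     simple_mode    34 0.3415145 0.04708620 4.077497e-13 1.407077 1.283031 1.543115
#> 5   weighted_mode    34 0.3582884 0.03474660 6.253947e-25 1.430878 1.336675 1.531721
print(report$sensitivity)
#> Sensitivity report
#>   Cochran's Q: 26.163 (df=33), p=0.795
#>   Egger intercept: -0.0025 (se 0.0031), p=0.439
#>   MR-PRESSO global p=0.872, 0 outlier(s) flagged
#>   Leave-one-out: 35 rows
```

Of the 40 generated instruments, 34 pass the `p < 1e-5` / `F ≥ 10`
screen. All five estimators recover the planted log-odds effect of
0.35 (IVW 0.346, OR 1.41), the classification rule calls the signal
causal and consistent, and the sensitivity suite is quiet: no
heterogeneity (Q p = 0.80), no directional pleiotropy (intercept
p = 0.44), no MR-PRESSO outliers.

The case-control stage runs on a simulated 75-subject cohort
(28 healthy controls, 20 cognitively normal patients, 27 demented
patients):

```r
coh <- simulate_cohort(seed = 42)
evaluate_biomarker(coh, "Subdoligranulum", seed = 42)
#>             taxon        H df       pval p_bonferroni      p_fdr     eta2_h
#> 1 Subdoligranulum 5.094141  2 0.07831073    0.3915536 0.09788841 0.04297419
#>   power       auc    auc_lo   auc_hi      cutoff sensitivity specificity
#> 1  0.42 0.6289683 0.4695106 0.771164 0.000497999   0.7777778   0.5714286
#>    accuracy pearson_r_mmse   pearson_p
#> 1 0.6727273     -0.3099917 0.006798925
```

One row per taxon: the three-group Kruskal-Wallis H with raw,
Bonferroni- and FDR-adjusted p-values (across the cohort's five taxa),
the η²_H effect size, simulated power at the moment-fitted group
parameters, the PDD-vs-HC ROC AUC with a stratified-bootstrap 95% CI,
the Youden-optimal abundance cutoff with its sensitivity / specificity
/ accuracy, and the Pearson correlation between abundance and MMSE
(here r = −0.31, p = 0.007, matching the generator's target).

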