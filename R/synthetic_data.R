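# Synthetic-data generators with known ground truth: GWAS summary
# statistics under a linear causal model with configurable pleiotropy,
# mediation triplets, block LD structure, and three-group abundance
# cohorts.

#' Generative parameters for a synthetic GWAS pair
#'
#' @param beta_causal true causal effect of the exposure on the outcome
#'   (log-odds per unit exposure for a binary outcome).
#' @param j_snps number of instruments.
#' @param n_exp,n_out GWAS sample sizes for the exposure and outcome.
#' @param prop_invalid fraction of instruments with a horizontal
#'   pleiotropic path to the outcome, in `[0, 1]`.
#' @param pleio_mean,pleio_sd distribution of the pleiotropic effects.
#' @param pleio_oriented when TRUE the pleiotropic effect acts relative
#'   to the exposure-increasing allele (`sign(gamma) * alpha`), so a
#'   non-zero `pleio_mean` is directional pleiotropy that survives the
#'   instrument re-orientation MR-Egger performs; when FALSE (default)
#'   alpha is added in the reported-allele frame, which - with true
#'   instrument effects symmetric around zero - contaminates the Wald
#'   ratios symmetrically.
#' @param inside_cor correlation between pleiotropic effects and
#'   instrument strength; non-zero values violate the InSIDE assumption
#'   that MR-Egger requires.
#' @param seed integer seed recorded verbatim and used by the generator.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(beta_causal = 0, j_snps = 50, n_exp = 5e4,
                             n_out = 5e4, prop_invalid = 0, pleio_mean = 0,
                             pleio_sd = 0, pleio_oriented = FALSE,
                             inside_cor = 0, seed = 1L) {
  stopifnot(prop_invalid >= 0, prop_invalid <= 1, j_snps >= 1,
            n_exp > 1, n_out > 1, abs(inside_cor) <= 1)
  structure(list(
    beta_causal = beta_causal, j_snps = as.integer(j_snps),
    n_exp = n_exp, n_out = n_out, prop_invalid = prop_invalid,
    pleio_mean = pleio_mean, pleio_sd = pleio_sd,
    pleio_oriented = isTRUE(pleio_oriented),
    inside_cor = inside_cor, seed = as.integer(seed)
  ), class = "simulation_truth")
}

# Per-allele standard error of a GWAS effect at frequency maf and size n.
.gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

# Draw true instrument effects ~ N(0, gamma_sd^2); for the first
# round(frac_strong * j) instruments, redraw until the true F-statistic
# (gamma/se)^2 exceeds min_f.
.draw_gamma <- function(j, se, gamma_sd, min_f, frac_strong) {
  gamma <- stats::rnorm(j, 0, gamma_sd)
  n_strong <- round(frac_strong * j)
  if (n_strong > 0) {
    idx <- seq_len(n_strong)
    for (iter in seq_len(10000L)) {
      weak <- idx[(gamma[idx] / se[idx])^2 < min_f]
      if (!length(weak)) break
      gamma[weak] <- stats::rnorm(length(weak), 0, gamma_sd)
      if (iter == 10000L) {
        stop("cannot satisfy instrument-strength condition; increase ",
             "gamma_sd or the sample size")
      }
    }
  }
  gamma
}

.build_table <- function(snp, chrom, pos, maf, beta_true, se, n, trait_id,
                         trait_type) {
  beta_hat <- stats::rnorm(length(snp), beta_true, se)
  pval <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), .Machine$double.xmin)
  summary_stats(data.frame(
    snp = snp, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",   # non-palindromic by design
    beta = beta_hat, se = se, pval = pval, eaf = maf, n = n,
    stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type, check = FALSE)
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Per variant j: frequency from `maf_range`; true instrument effect
#' `gamma_j ~ N(0, gamma_sd^2)` conditioned so that a configurable
#' fraction exceeds `min_f` in true F-statistic (the default matches the
#' `p < 1e-5` screen the pipeline applies to real instruments); a
#' pleiotropic effect `alpha_j` for the invalid fraction; true outcome
#' effect `beta_causal * gamma_j + alpha_j` (with alpha applied in the
#' oriented frame when `truth$pleio_oriented`); observed
#' effects drawn around the truth with standard errors
#' `1/sqrt(2 maf (1-maf) n)`; p-values from the z statistic. When
#' `ld_blocks` is given, the returned lookup has `r2 = rho^2` within
#' consecutive blocks and 0 across. Fully reproducible from
#' `truth$seed`.
#'
#' @param truth a [simulation_truth()].
#' @param maf_range interval for the uniform effect-allele frequency.
#' @param ld_blocks NULL or `list(block_size =, rho =)`.
#' @param gamma_sd standard deviation of true instrument effects.
#' @param min_f conditioning threshold on the true F-statistic; the
#'   default `qnorm(1 - 5e-6)^2` (about 19.5) mirrors selection at
#'   `p < 1e-5`.
#' @param frac_strong fraction of instruments conditioned to exceed
#'   `min_f` (default 1).
#' @return List with `exposure` and `outcome` ([summary_stats()] tables),
#'   `ld` (an [ld_lookup()]), and `truth` extended with the realized
#'   `gamma`, `alpha` and `invalid` vectors.
#' @export
simulate_summary_stats <- function(truth, maf_range = c(0.05, 0.5),
                                   ld_blocks = NULL, gamma_sd = 0.05,
                                   min_f = stats::qnorm(1 - 5e-6)^2,
                                   frac_strong = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing interval within (0, 1)")
  }
  with_seed(truth$seed, {
    j <- truth$j_snps
    snp <- sprintf("rs%06d", seq_len(j))
    chrom <- rep("1", j)
    pos <- seq_len(j) * 50000L
    maf <- stats::runif(j, maf_range[1], maf_range[2])
    se_exp <- .gwas_se(maf, truth$n_exp)
    se_out <- .gwas_se(maf, truth$n_out)
    gamma <- .draw_gamma(j, se_exp, gamma_sd, min_f, frac_strong)
    n_invalid <- round(truth$prop_invalid * j)
    invalid <- seq_len(j) <= n_invalid
    alpha <- numeric(j)
    if (n_invalid > 0) {
      z <- stats::rnorm(n_invalid)
      if (truth$inside_cor != 0) {
        zg <- scale(abs(gamma[invalid]))[, 1]
        if (any(!is.finite(zg))) zg <- rep(0, n_invalid)
        z <- truth$inside_cor * zg + sqrt(1 - truth$inside_cor^2) * z
      }
      alpha[invalid] <- truth$pleio_mean + truth$pleio_sd * z
    }
    gamma_out <- truth$beta_causal * gamma +
      if (truth$pleio_oriented) sign(gamma) * alpha else alpha
    exposure <- .build_table(snp, chrom, pos, maf, gamma, se_exp,
                             truth$n_exp, "synthetic_exposure",
                             "continuous")
    outcome <- .build_table(snp, chrom, pos, maf, gamma_out, se_out,
                            truth$n_out, "synthetic_outcome", "binary")
    ld <- if (is.null(ld_blocks)) {
      ld_lookup()
    } else {
      ld_block_matrix(j, ld_blocks$block_size, ld_blocks$rho, snp = snp)
    }
    truth$gamma <- gamma
    truth$alpha <- alpha
    truth$invalid <- invalid
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' Block-diagonal LD lookup
#'
#' Consecutive blocks of `block_size` variants share `r2 = rho^2`;
#' cross-block pairs have r2 = 0 and the diagonal is 1.
#'
#' @param j_snps number of variants.
#' @param block_size variants per block (last block may be smaller).
#' @param rho within-block correlation, in `[0, 1]`.
#' @param snp optional identifiers (default `rs000001`, ...).
#' @return An [ld_lookup()].
#' @export
ld_block_matrix <- function(j_snps, block_size, rho,
                            snp = sprintf("rs%06d", seq_len(j_snps))) {
  stopifnot(rho >= 0, rho <= 1, block_size >= 1)
  if (rho == 0) return(ld_lookup())
  block <- ceiling(seq_len(j_snps) / block_size)
  a <- character(0); b <- character(0)
  for (g in unique(block)) {
    members <- which(block == g)
    if (length(members) < 2L) next
    pairs <- utils::combn(members, 2L)
    a <- c(a, snp[pairs[1, ]])
    b <- c(b, snp[pairs[2, ]])
  }
  ld_lookup(a, b, rep(rho^2, length(a)))
}

#' Simulate a mediation triplet of GWAS summary tables
#'
#' Generates three traits - exposure, mediator, outcome - with
#' independent instrument sets: `j_exp` variants instrument the exposure
#' and `j_med` the mediator. The exposure affects the mediator with
#' effect `beta1`, the mediator affects the outcome with `beta2`, and
#' the exposure has total effect `beta1 * beta2 + direct` on the
#' outcome. Each trait's table covers all variants (exposure instruments
#' appear in the mediator and outcome tables through their induced
#' effects), so instrument re-selection behaves as it would on real
#' catalogs.
#'
#' @param beta1,beta2,direct path coefficients.
#' @param j_exp,j_med instruments per relation.
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param seed integer seed.
#' @param gamma_sd,min_f,maf_range see [simulate_summary_stats()].
#' @return List with `exposure`, `mediator`, `outcome` (tables) and
#'   `truth`, which records the implied proportion
#'   `beta1 beta2 / (beta1 beta2 + direct)` (NA, with a flag, when the
#'   total effect is zero).
#' @export
simulate_mediation_triplet <- function(beta1, beta2, direct, j_exp = 100,
                                       j_med = 100, n_exp = 1e5,
                                       n_med = 1e5, n_out = 1e5, seed = 1L,
                                       gamma_sd = 0.05,
                                       min_f = stats::qnorm(1 - 5e-6)^2,
                                       maf_range = c(0.05, 0.5)) {
  with_seed(seed, {
    j <- j_exp + j_med
    snp <- c(sprintf("rsE%05d", seq_len(j_exp)),
             sprintf("rsM%05d", seq_len(j_med)))
    chrom <- rep("1", j)
    pos <- seq_len(j) * 50000L
    maf <- stats::runif(j, maf_range[1], maf_range[2])
    is_exp <- seq_len(j) <= j_exp
    gamma_e <- .draw_gamma(j_exp, .gwas_se(maf[is_exp], n_exp), gamma_sd,
                           min_f, 1)
    gamma_m <- .draw_gamma(j_med, .gwas_se(maf[!is_exp], n_med), gamma_sd,
                           min_f, 1)
    total <- beta1 * beta2 + direct
    true_exp <- c(gamma_e, numeric(j_med))
    true_med <- c(beta1 * gamma_e, gamma_m)
    true_out <- c(total * gamma_e, beta2 * gamma_m)
    exposure <- .build_table(snp, chrom, pos, maf, true_exp,
                             .gwas_se(maf, n_exp), n_exp,
                             "synthetic_exposure", "continuous")
    mediator <- .build_table(snp, chrom, pos, maf, true_med,
                             .gwas_se(maf, n_med), n_med,
                             "synthetic_mediator", "continuous")
    outcome <- .build_table(snp, chrom, pos, maf, true_out,
                            .gwas_se(maf, n_out), n_out,
                            "synthetic_outcome", "binary")
    truth <- list(beta1 = beta1, beta2 = beta2, direct = direct,
                  beta_total = total,
                  implied_proportion = if (total == 0) NA_real_ else
                    beta1 * beta2 / total,
                  total_is_zero = total == 0,
                  j_exp = j_exp, j_med = j_med, seed = as.integer(seed))
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth)
  })
}

#' Per-taxon generative specification for cohort simulation
#'
#' Abundances are zero-inflated log-normal: with probability `zero_p`
#' the taxon is absent; otherwise abundance is log-normal with the
#' group's mean (`meanlog = log(mean) - sdlog^2/2`).
#'
#' @param taxon taxon name.
#' @param mean_hc,mean_pdnc,mean_pdd group mean relative abundances.
#' @param sdlog log-scale standard deviation (default 0.9, i.e. a
#'   coefficient of variation near 1, typical of genus-level relative
#'   abundances).
#' @param zero_p zero-inflation probability (default 0.1).
#' @return One-row data.frame; rbind rows to build a multi-taxon spec.
#' @export
cohort_taxon_spec <- function(taxon, mean_hc, mean_pdnc, mean_pdd,
                              sdlog = 0.9, zero_p = 0.1) {
  stopifnot(mean_hc > 0, mean_pdnc > 0, mean_pdd > 0, sdlog > 0,
            zero_p >= 0, zero_p < 1)
  data.frame(taxon = taxon, mean_hc = mean_hc, mean_pdnc = mean_pdnc,
             mean_pdd = mean_pdd, sdlog = sdlog, zero_p = zero_p,
             stringsAsFactors = FALSE)
}

#' Default five-genus cohort specification
#'
#' Group mean relative abundances for the five genera the MR stage
#' flags, at magnitudes typical of genus-level gut metagenomes (central
#' values near 1e-3 to 1e-2).
#'
#' @return data.frame of [cohort_taxon_spec()] rows.
#' @export
default_taxa_spec <- function() {
  rbind(
    cohort_taxon_spec("Subdoligranulum", 0.000719, 0.000972, 0.001217),
    cohort_taxon_spec("Lachnospira",     0.010449, 0.004669, 0.003327),
    cohort_taxon_spec("Roseburia",       0.017804, 0.008067, 0.008942),
    cohort_taxon_spec("Butyricimonas",   0.000964, 0.002711, 0.003960),
    cohort_taxon_spec("Hungatella",      0.000437, 0.000437, 0.000646)
  )
}

.GROUPS <- c("HC", "PD-NC", "PDD")

#' Simulate a three-group case-control abundance cohort
#'
#' Subjects in three groups (healthy controls, cognitively normal
#' patients, demented patients) carry zero-inflated log-normal relative
#' abundances per taxon and an integer MMSE score (0-30). MMSE is drawn
#' around group means and linearly blended with the standardized
#' abundance of `cor_taxon` so that the latent construction targets
#' correlation `cor_r`; the achieved sample correlation is recorded in
#' the returned truth attribute.
#'
#' @param n_hc,n_pdnc,n_pdd group sizes (defaults 28 / 20 / 27).
#' @param taxa a taxa specification, see [cohort_taxon_spec()].
#' @param mmse_mean,mmse_sd named per-group MMSE means and standard
#'   deviations; the defaults are typical of such cohorts (controls near
#'   ceiling, demented patients far below).
#' @param cor_taxon taxon whose abundance is blended into MMSE.
#' @param cor_r target latent correlation, `|cor_r| < 1`.
#' @param seed integer seed.
#' @return An `abundance_cohort`: data.frame with `subject_id`, `group`
#'   (factor HC / PD-NC / PDD), `mmse`, and one column per taxon;
#'   attribute `"truth"` records the parameters and the achieved
#'   abundance-MMSE correlation.
#' @export
simulate_cohort <- function(n_hc = 28, n_pdnc = 20, n_pdd = 27,
                            taxa = default_taxa_spec(),
                            mmse_mean = c(HC = 29.18, `PD-NC` = 28.50,
                                          PDD = 19.30),
                            mmse_sd = c(HC = 0.90, `PD-NC` = 1.15,
                                        PDD = 4.10),
                            cor_taxon = taxa$taxon[1], cor_r = -0.316,
                            seed = 1L) {
  if (abs(cor_r) >= 1) stop("infeasible correlation: |cor_r| must be < 1")
  stopifnot(all(.GROUPS %in% names(mmse_mean)),
            all(.GROUPS %in% names(mmse_sd)),
            cor_taxon %in% taxa$taxon)
  with_seed(seed, {
    group <- factor(rep(.GROUPS, times = c(n_hc, n_pdnc, n_pdd)),
                    levels = .GROUPS)
    n <- length(group)
    abund <- matrix(0, n, nrow(taxa),
                    dimnames = list(NULL, taxa$taxon))
    for (t in seq_len(nrow(taxa))) {
      mu_g <- c(HC = taxa$mean_hc[t], `PD-NC` = taxa$mean_pdnc[t],
                PDD = taxa$mean_pdd[t])
      mu <- unname(mu_g[as.character(group)])
      meanlog <- log(mu) - taxa$sdlog[t]^2 / 2
      x <- stats::rlnorm(n, meanlog, taxa$sdlog[t])
      x[stats::runif(n) < taxa$zero_p[t]] <- 0
      abund[, t] <- x
    }
    over <- rowSums(abund) > 1
    if (any(over)) {  # relative abundances must sum to at most 1
      abund[over, ] <- abund[over, ] / rowSums(abund)[over] * 0.99
    }
    za <- abund[, cor_taxon]
    za <- if (stats::sd(za) > 0) (za - mean(za)) / stats::sd(za) else
      rep(0, n)
    noise <- stats::rnorm(n)
    mmse0 <- mmse_mean[as.character(group)] +
      mmse_sd[as.character(group)] * noise
    # Blend mmse0 with the abundance signal: mmse0 + lambda sd(mmse0) za
    # with lambda solving for overall correlation cor_r, so the target
    # covers both the between-group and within-group contributions.
    c0 <- stats::cor(za, mmse0)
    lambda <- -c0 + cor_r * sqrt((1 - c0^2) / (1 - cor_r^2))
    mmse_raw <- mmse0 + lambda * stats::sd(mmse0) * za
    mmse <- as.integer(pmin(30, pmax(0, round(mmse_raw))))
    cohort <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)), group = group,
      mmse = mmse, stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, as.data.frame(abund))
    truth <- list(
      n_hc = n_hc, n_pdnc = n_pdnc, n_pdd = n_pdd, cor_taxon = cor_taxon,
      target_r = cor_r,
      achieved_r = if (stats::sd(abund[, cor_taxon]) > 0 &&
                       stats::sd(mmse) > 0) {
        stats::cor(abund[, cor_taxon], mmse)
      } else NA_real_,
      seed = as.integer(seed)
    )
    structure(cohort, truth = truth,
              class = c("abundance_cohort", "data.frame"))
  })
}
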