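# Sensitivity diagnostics: heterogeneity, pleiotropy, outliers, influence.

#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance-weighted sum of squared deviations of the
#' per-variant Wald ratios from the fixed-effect IVW estimate, referred
#' to a chi-square distribution with `J - 1` degrees of freedom.
#'
#' @param hset a `harmonized_set` with at least 2 instruments.
#' @return List with `q`, `df` and `pval`.
#' @export
cochran_q <- function(hset) {
  j <- n_instruments(hset)
  if (j < 2L) stop("Cochran's Q requires at least 2 instruments")
  est <- mr_ivw(hset, model = "fixed")
  q <- est$extra$q
  list(q = q, df = j - 1L, pval = stats::pchisq(q, df = j - 1L,
                                                lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept triple from the [mr_egger()] fit (the same
#' computation; identical numbers). An intercept distinguishable from
#' zero indicates directional horizontal pleiotropy.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @return List with `intercept`, `se` and `pval`.
#' @export
egger_intercept_test <- function(hset) {
  fit <- mr_egger(hset)
  list(intercept = fit$extra$intercept, se = fit$extra$intercept_se,
       pval = fit$extra$intercept_p)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The observed residual sum of squares is
#' `sum_j w_j (beta_out_j - bhat_(-j) beta_exp_j)^2` with
#' `w_j = 1/se_out_j^2` and `bhat_(-j)` the leave-one-out
#' inverse-variance-weighted slope. A null distribution is built from
#' `n_sim` parametric simulations drawing exposure effects around their
#' observed values and outcome effects around the leave-one-out fitted
#' values. The global p-value is the fraction of simulated RSS at or
#' above the observed one; per-variant outlier p-values compare each
#' observation's contribution with its simulated distribution and are
#' Bonferroni-flagged at `outlier_alpha`. The outlier-corrected estimate
#' is IVW on the unflagged subset, and the distortion test compares the
#' observed shift against shifts from removing equally many random
#' variants. Monte-Carlo p-values are floored at `1/(n_sim + 1)`.
#'
#' @param hset a `harmonized_set` with at least 4 instruments.
#' @param n_sim parametric simulations (default 1000).
#' @param outlier_alpha family-wise flagging level (default 0.05).
#' @param seed integer seed; all draws are reproducible from it.
#' @return List with `global_p`, `outlier_p` (named per variant),
#'   `outlier_flags`, `n_outliers`, `raw_estimate`, `corrected_estimate`
#'   (IVW objects; corrected is NULL when nothing is flagged) and
#'   `distortion_p` (NA when nothing is flagged).
#' @export
mr_presso <- function(hset, n_sim = 1000, outlier_alpha = 0.05, seed = 1L) {
  j <- n_instruments(hset)
  if (j < 4L) stop("insufficient instruments for MR-PRESSO (need >= 4)")
  x <- hset$beta_exp; y <- hset$beta_out
  w <- 1 / hset$se_out^2
  # leave-one-out IVW slopes of y on x (no intercept), weights w
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  b_loo <- (sxy - w * x * y) / (sxx - w * x^2)
  contrib_obs <- w * (y - b_loo * x)^2
  rss_obs <- sum(contrib_obs)
  with_seed(seed, {
    xs <- matrix(stats::rnorm(j * n_sim, mean = x, sd = hset$se_exp), j)
    ys <- matrix(stats::rnorm(j * n_sim, mean = b_loo * x,
                              sd = hset$se_out), j)
    sxx_s <- colSums(w * xs^2)
    sxy_s <- colSums(w * xs * ys)
    b_loo_s <- (rep(sxy_s, each = j) - w * xs * ys) /
      (rep(sxx_s, each = j) - w * xs^2)
    contrib_s <- w * (ys - b_loo_s * xs)^2
    rss_s <- colSums(contrib_s)
    global_p <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + rowSums(contrib_s >= contrib_obs)) / (n_sim + 1)
    names(outlier_p) <- hset$snp
    flags <- outlier_p < outlier_alpha / j
    raw <- mr_ivw(hset)
    corrected <- NULL
    distortion_p <- NA_real_
    if (any(flags) && sum(!flags) >= 2L) {
      corrected <- mr_ivw(.subset_hset(hset, !flags))
      d_obs <- raw$beta - corrected$beta
      n_out <- sum(flags)
      d_null <- vapply(seq_len(n_sim), function(s) {
        drop <- sample.int(j, n_out)
        keep <- setdiff(seq_len(j), drop)
        b_sub <- sum(w[keep] * x[keep] * y[keep]) / sum(w[keep] * x[keep]^2)
        raw$beta - b_sub
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    }
    list(global_p = global_p, outlier_p = outlier_p, outlier_flags = flags,
         n_outliers = sum(flags), raw_estimate = raw,
         corrected_estimate = corrected, distortion_p = distortion_p)
  })
}

.subset_hset <- function(hset, keep) {
  out <- hset
  for (f in c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
              "eaf_exp", "eaf_out")) {
    out[[f]] <- hset[[f]][keep]
  }
  out$actions <- hset$actions[hset$actions %in% c("kept", "flipped")][keep]
  out
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate with each instrument omitted in turn,
#' plus the all-instrument row (labelled `"All"`). A single influential
#' variant shows up as an omission row departing from the rest.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @param model IVW variant, see [mr_ivw()].
#' @return data.frame with columns `omitted_snp`, `beta`, `se`, `pval`;
#'   `J + 1` rows for J instruments.
#' @export
leave_one_out <- function(hset, model = "multiplicative_random") {
  j <- n_instruments(hset)
  if (j < 3L) stop("leave-one-out requires at least 3 instruments")
  rows <- lapply(seq_len(j), function(k) {
    est <- mr_ivw(.subset_hset(hset, seq_len(j) != k), model = model)
    data.frame(omitted_snp = hset$snp[k], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  full <- mr_ivw(hset, model = model)
  out <- rbind(do.call(rbind, rows),
               data.frame(omitted_snp = "All", beta = full$beta,
                          se = full$se, pval = full$pval,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Full sensitivity report for a harmonized instrument set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-out table, each run when the instrument count allows it.
#'
#' @param hset a `harmonized_set`.
#' @param seed integer seed for MR-PRESSO.
#' @param n_sim MR-PRESSO simulation count.
#' @param run_presso set FALSE to skip the (comparatively costly)
#'   MR-PRESSO step.
#' @return A `sensitivity_report` list with elements `q`, `egger`,
#'   `presso`, `loo` (NULL where inapplicable).
#' @export
sensitivity_report <- function(hset, seed = 1L, n_sim = 1000,
                               run_presso = TRUE) {
  j <- n_instruments(hset)
  structure(list(
    q = if (j >= 2L) cochran_q(hset) else NULL,
    egger = if (j >= 3L) egger_intercept_test(hset) else NULL,
    presso = if (run_presso && j >= 4L) {
      mr_presso(hset, n_sim = n_sim, seed = seed)
    } else NULL,
    loo = if (j >= 3L) leave_one_out(hset) else NULL
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report\n")
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q: %.3f (df=%d), p=%.3g\n",
                x$q$q, x$q$df, x$q$pval))
  }
  if (!is.null(x$egger)) {
    cat(sprintf("  Egger intercept: %.4f (se %.4f), p=%.3g\n",
                x$egger$intercept, x$egger$se, x$egger$pval))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p=%.3g, %d outlier(s) flagged\n",
                x$presso$global_p, x$presso$n_outliers))
  }
  if (!is.null(x$loo)) {
    cat(sprintf("  Leave-one-out: %d rows\n", nrow(x$loo)))
  }
  invisible(x)
}
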