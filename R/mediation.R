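# Pipeline orchestration: single-direction MR runs, bidirectional MR,
# and two-step mediation with proportion mediated.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of a full MR run. `ld = NULL` skips
#' the clumping step (appropriate when instruments are already
#' independent, as in the synthetic generators); real-data use requires
#' the caller to supply reference-panel r2 values via [ld_lookup()].
#'
#' @param p_threshold,f_min instrument selection, see
#'   [select_instruments()].
#' @param r2_threshold,window_kb clumping, see [ld_clump()].
#' @param palindrome_eaf_band harmonization, see [harmonize()].
#' @param ld an [ld_lookup()] or NULL.
#' @param ivw_model IVW variant, see [mr_ivw()].
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param sensitivity run the sensitivity suite in pipeline reports.
#' @param run_presso include MR-PRESSO in the sensitivity suite.
#' @param n_sim MR-PRESSO simulation count.
#' @param alpha significance level for [classify_causal_signal()].
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_threshold = 1e-5, f_min = 10, r2_threshold = 0.01,
                      window_kb = 10000, palindrome_eaf_band = 0.42,
                      ld = NULL, ivw_model = "multiplicative_random",
                      n_boot = 1000, sensitivity = TRUE, run_presso = TRUE,
                      n_sim = 1000, alpha = 0.05) {
  structure(list(
    p_threshold = p_threshold, f_min = f_min, r2_threshold = r2_threshold,
    window_kb = window_kb, palindrome_eaf_band = palindrome_eaf_band,
    ld = ld, ivw_model = ivw_model, n_boot = n_boot,
    sensitivity = sensitivity, run_presso = run_presso, n_sim = n_sim,
    alpha = alpha
  ), class = "mr_config")
}

#' Run the full MR pipeline for one exposure-outcome pair
#'
#' Select instruments, clump (when an LD lookup is configured),
#' harmonize, estimate with all applicable methods, classify the signal
#' and (optionally) run the sensitivity suite. When fewer than two
#' instruments survive the report carries status `"inconclusive"`
#' instead of raising an error.
#'
#' @param exposure,outcome [summary_stats()] tables.
#' @param config an [mr_config()].
#' @param seed integer seed for bootstrap and simulation steps.
#' @return An `mr_report` list: `exposure_id`, `outcome_id`, `status`
#'   (`"ok"` or `"inconclusive"`), `hset`, `estimates`, `classification`,
#'   `sensitivity`.
#' @export
run_mr <- function(exposure, outcome, config = mr_config(), seed = 1L) {
  report <- structure(list(
    exposure_id = attr(exposure, "trait_id"),
    outcome_id = attr(outcome, "trait_id"),
    status = "inconclusive", hset = NULL, estimates = NULL,
    classification = "null", sensitivity = NULL
  ), class = "mr_report")
  iv <- select_instruments(exposure, config$p_threshold, config$f_min)
  if (!is.null(config$ld)) {
    iv <- ld_clump(iv, config$ld, config$r2_threshold, config$window_kb)
  }
  if (nrow(iv) == 0L) return(report)
  hs <- tryCatch(harmonize(iv, outcome, config$palindrome_eaf_band),
                 error = function(e) NULL)
  if (is.null(hs) || n_instruments(hs) < 2L) return(report)
  report$hset <- hs
  report$estimates <- mr_estimate_all(hs, seed = seed,
                                      n_boot = config$n_boot,
                                      ivw_model = config$ivw_model)
  report$classification <- classify_causal_signal(report$estimates,
                                                  alpha = config$alpha)
  if (config$sensitivity) {
    report$sensitivity <- sensitivity_report(hs, seed = seed,
                                             n_sim = config$n_sim,
                                             run_presso = config$run_presso)
  }
  report$status <- "ok"
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR report: %s -> %s [%s]\n", x$exposure_id, x$outcome_id,
              x$status))
  if (x$status == "ok") {
    cat(sprintf("  classification: %s, %d instrument(s)\n",
                x$classification, n_instruments(x$hset)))
    print(x$estimates[, c("method", "n_snp", "beta", "se", "pval", "or_",
                          "ci_low", "ci_high")])
  }
  invisible(x)
}

#' Bidirectional MR
#'
#' Runs the full pipeline in both directions: trait A as exposure of
#' trait B, then trait B as exposure of trait A, each with
#' direction-specific instrument selection. A direction in which no
#' usable instrument set survives is reported as inconclusive rather
#' than raising an error.
#'
#' @param table_a,table_b [summary_stats()] tables.
#' @param config an [mr_config()].
#' @param seed integer seed.
#' @return List with elements `forward` (a to b) and `reverse` (b to a),
#'   each an `mr_report`.
#' @export
bidirectional_mr <- function(table_a, table_b, config = mr_config(),
                             seed = 1L) {
  list(forward = run_mr(table_a, table_b, config, seed = seed),
       reverse = run_mr(table_b, table_a, config, seed = seed + 1L))
}

#' Two-step mediation with proportion mediated
#'
#' Combines three IVW estimates - exposure on mediator (beta1), mediator
#' on outcome (beta2), exposure on outcome (total) - into the indirect
#' effect `beta1 * beta2`, its delta-method standard error
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`, and the proportion mediated
#' `beta1 * beta2 / beta_total`. The proportion interval propagates the
#' indirect-effect confidence interval over the total effect treated as
#' fixed - a deliberate simplification, flagged in the output docs.
#'
#' @param exp_to_med,med_to_out,exp_to_out `mr_estimate` objects (IVW)
#'   for the three relations.
#' @return A `mediation_result` list with `beta_total`, `beta1`, `se1`,
#'   `beta2`, `se2`, `indirect`, `se_indirect`, `proportion`,
#'   `proportion_ci` (length-2), `direction_ok`.
#' @export
two_step_mediation <- function(exp_to_med, med_to_out, exp_to_out) {
  b1 <- exp_to_med$beta; s1 <- exp_to_med$se
  b2 <- med_to_out$beta; s2 <- med_to_out$se
  bt <- exp_to_out$beta
  if (bt == 0) stop("undefined proportion: total effect is zero")
  indirect <- b1 * b2
  se_ind <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  proportion <- indirect / bt
  ci_ind <- indirect + c(-1.96, 1.96) * se_ind
  proportion_ci <- sort(ci_ind / bt)
  structure(list(
    beta_total = bt, beta1 = b1, se1 = s1, beta2 = b2, se2 = s2,
    indirect = indirect, se_indirect = se_ind, proportion = proportion,
    proportion_ci = proportion_ci,
    direction_ok = sign(indirect) == sign(bt)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("Mediation: indirect=%.4f (se %.4f), total=%.4f, ",
                     "proportion=%.1f%% [%.1f%%, %.1f%%]%s\n"),
              x$indirect, x$se_indirect, x$beta_total, 100 * x$proportion,
              100 * x$proportion_ci[1], 100 * x$proportion_ci[2],
              if (x$direction_ok) "" else " (direction mismatch)"))
  invisible(x)
}

#' Screen candidate mediators between an exposure and an outcome
#'
#' For each mediator table, estimates exposure-to-mediator (beta1) and
#' mediator-to-outcome (beta2) by the full pipeline, retains mediators
#' where both steps are classified `significant_consistent`, and ranks
#' the retained mediators by absolute proportion mediated. Each step
#' uses its own instrument selection from the relevant table.
#'
#' @param exposure a [summary_stats()] table.
#' @param mediators named list of [summary_stats()] tables.
#' @param outcome a [summary_stats()] table.
#' @param config an [mr_config()]. `display_p` (the per-step IVW p-value
#'   used only to filter the returned rows) defaults to `config$alpha`.
#' @param seed integer seed.
#' @return data.frame with one row per retained mediator: `mediator_id`,
#'   `beta1`, `se1`, `beta2`, `se2`, `beta_total`, `indirect`,
#'   `se_indirect`, `proportion`, `proportion_lo`, `proportion_hi`,
#'   `direction_ok`; sorted by `abs(proportion)` descending. Zero rows
#'   when no mediator passes.
#' @export
mediation_screen <- function(exposure, mediators, outcome,
                             config = mr_config(), seed = 1L) {
  stopifnot(length(mediators) >= 1L)
  if (is.null(names(mediators))) {
    names(mediators) <- vapply(mediators, function(m) attr(m, "trait_id"), "")
  }
  total_rep <- run_mr(exposure, outcome, config, seed = seed)
  if (total_rep$status != "ok") {
    stop("total-effect MR inconclusive: no usable instruments from ",
         "exposure to outcome")
  }
  total_ivw <- .ivw_from_report(total_rep)
  rows <- list()
  i <- 0L
  for (med_id in names(mediators)) {
    i <- i + 1L
    step1 <- run_mr(exposure, mediators[[med_id]], config,
                    seed = seed + 100L + i)
    step2 <- run_mr(mediators[[med_id]], outcome, config,
                    seed = seed + 200L + i)
    if (step1$status != "ok" || step2$status != "ok") next
    if (step1$classification != "significant_consistent" ||
        step2$classification != "significant_consistent") next
    res <- two_step_mediation(.ivw_from_report(step1),
                              .ivw_from_report(step2), total_ivw)
    rows[[med_id]] <- data.frame(
      mediator_id = med_id, beta1 = res$beta1, se1 = res$se1,
      beta2 = res$beta2, se2 = res$se2, beta_total = res$beta_total,
      indirect = res$indirect, se_indirect = res$se_indirect,
      proportion = res$proportion, proportion_lo = res$proportion_ci[1],
      proportion_hi = res$proportion_ci[2],
      direction_ok = res$direction_ok, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(
      mediator_id = character(0), beta1 = numeric(0), se1 = numeric(0),
      beta2 = numeric(0), se2 = numeric(0), beta_total = numeric(0),
      indirect = numeric(0), se_indirect = numeric(0),
      proportion = numeric(0), proportion_lo = numeric(0),
      proportion_hi = numeric(0), direction_ok = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$proportion)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rebuild the IVW mr_estimate from a pipeline report's estimates table.
.ivw_from_report <- function(report) {
  k <- which(report$estimates$method == "ivw")
  if (!length(k)) stop("report carries no IVW estimate")
  .mr_estimate("ivw", report$estimates$beta[k], report$estimates$se[k],
               report$estimates$pval[k], report$estimates$n_snp[k])
}
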