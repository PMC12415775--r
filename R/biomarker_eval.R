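# Case-control biomarker evaluation: group testing with effect size and
# simulated power, multiplicity adjustment, ROC/AUC with Youden cutoff
# and confusion matrix, marker combination, correlation with MMSE.

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank-based H statistic with `k - 1` degrees of freedom
#' (computed by [stats::kruskal.test()]).
#'
#' @param values numeric vector.
#' @param groups group labels, at least two non-empty groups.
#' @return List with `statistic` (H), `df`, `pval`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (length(unique(values)) == 1L) {
    # every observation tied: no evidence of group differences
    return(list(statistic = 0, df = nlevels(groups) - 1L, pval = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       pval = kt$p.value)
}

#' Eta-squared effect size from the Kruskal-Wallis H statistic
#'
#' `(H - k + 1) / (n - k)`; zero at the null expectation `H = k - 1`.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k number of groups.
#' @param n total sample size (`n > k`).
#' @return Numeric effect size.
#' @export
eta_squared_h <- function(H, k, n) {
  if (n <= k) stop("n must exceed the number of groups")
  (H - k + 1) / (n - k)
}

#' Multiplicity adjustment of p-values
#'
#' `bonferroni`: `min(1, m p)`; `bh_fdr`: Benjamini-Hochberg step-up
#' with monotonicity enforcement. Input order is preserved and no
#' adjusted value is ever below its input.
#'
#' @param pvals numeric vector in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = switch(method, bonferroni = "bonferroni",
                                         bh_fdr = "BH"))
}

.binary_labels <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  labels == positive
}

#' ROC curve and AUC
#'
#' The curve sweeps every threshold over the observed scores (predicting
#' positive at `score >= t`); the AUC is computed as the Mann-Whitney
#' concordance probability with ties counted half, which equals the
#' trapezoidal area under the curve. The confidence interval comes from
#' a seeded stratified bootstrap (resampling within each class).
#'
#' @param scores numeric marker values.
#' @param labels class labels; `positive` names the disease class.
#' @param positive value of `labels` treated as positive (default TRUE
#'   for logical labels).
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed integer seed for the bootstrap; `NULL` skips the CI.
#' @param conf confidence level (default 0.95).
#' @return List with `curve` (data.frame `threshold`, `sensitivity`,
#'   `specificity`), `auc`, and `auc_ci` (NULL without a seed).
#' @export
roc_auc <- function(scores, labels, positive = TRUE, n_boot = 2000,
                    seed = NULL, conf = 0.95) {
  y <- .binary_labels(labels, positive)
  if (!any(y) || all(y)) stop("both classes must be present")
  stopifnot(length(scores) == length(y), !any(is.na(scores)))
  auc <- .auc_rank(scores, y)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(scores[y] >= t),
                              numeric(1))),
    specificity = c(1, vapply(thr, function(t) mean(scores[!y] < t),
                              numeric(1)))
  )
  ci <- NULL
  if (!is.null(seed)) {
    pos_idx <- which(y); neg_idx <- which(!y)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      ip <- sample(pos_idx, length(pos_idx), replace = TRUE)
      io <- sample(neg_idx, length(neg_idx), replace = TRUE)
      s <- c(scores[ip], scores[io])
      .auc_rank(s, c(rep(TRUE, length(ip)), rep(FALSE, length(io))))
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  list(curve = curve, auc = auc, auc_ci = ci)
}

# Mann-Whitney AUC via ranks; ties counted half.
.auc_rank <- function(scores, y) {
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal cutoff and confusion matrix from a ROC curve
#'
#' Picks the cutoff maximizing Youden's J (sensitivity + specificity -
#' 1), taking the lowest such cutoff on ties. The marker's risk
#' direction is auto-detected from which side of 0.5 its AUC falls:
#' risk markers predict positive at `score >= cutoff`, protective
#' markers at `score <= cutoff`. Constant scores yield a degenerate
#' report (J = 0) with a warning.
#'
#' @param scores,labels,positive as in [roc_auc()].
#' @return A `diagnostic_report` list: `cutoff`, `direction` (`"risk"`
#'   or `"protective"`), `sensitivity`, `specificity`, `accuracy`,
#'   `youden_j`, `confusion` (2x2 integer matrix), `auc`, `degenerate`.
#' @export
optimal_cutoff_confusion <- function(scores, labels, positive = TRUE) {
  y <- .binary_labels(labels, positive)
  if (!any(y) || all(y)) stop("both classes must be present")
  auc <- .auc_rank(scores, y)
  direction <- if (auc >= 0.5) "risk" else "protective"
  pred_at <- function(cut) {
    if (direction == "risk") scores >= cut else scores <= cut
  }
  cand <- sort(unique(scores))
  stats_at <- vapply(cand, function(cut) {
    p <- pred_at(cut)
    sens <- mean(p[y]); spec <- mean(!p[!y])
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  degenerate <- length(cand) == 1L || max(stats_at[1, ]) <= 0
  if (length(cand) == 1L) {
    warning("constant scores: degenerate classifier (Youden J = 0)")
  }
  best <- which(stats_at[1, ] == max(stats_at[1, ]))[1]  # lowest cutoff
  cutoff <- cand[best]
  p <- pred_at(cutoff)
  tp <- sum(p & y); fn <- sum(!p & y)
  fp <- sum(p & !y); tn <- sum(!p & !y)
  confusion <- matrix(as.integer(c(tp, fn, fp, tn)), 2L, 2L,
                      dimnames = list(predicted = c("positive", "negative"),
                                      actual = c("positive", "negative")))
  structure(list(
    cutoff = cutoff, direction = direction,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(y), youden_j = max(stats_at[1, ]),
    confusion = confusion, auc = auc, degenerate = degenerate
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf(paste0("Diagnostic report: AUC=%.3f, cutoff=%g (%s), ",
                     "sens=%.2f, spec=%.2f, acc=%.2f\n"),
              x$auc, x$cutoff, x$direction, x$sensitivity, x$specificity,
              x$accuracy))
  print(x$confusion)
  invisible(x)
}

# Binary logistic regression by iteratively reweighted least squares.
# Rank-deficient designs have aliased columns dropped (coefficient NA),
# so duplicated markers leave the fitted score unchanged.
.irls_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xr <- X[, keep, drop = FALSE]
  p <- ncol(Xr)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xr %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(Xr, z, w)
    beta <- fit$coefficients
    eta <- drop(Xr %*% beta)
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(Xr %*% beta)
  separation <- !converged && max(abs(eta)) > 20 &&
    all((eta > 0) == (y == 1))
  coefs <- rep(NA_real_, ncol(X))
  names(coefs) <- colnames(X)
  coefs[keep] <- beta
  list(coefficients = coefs, linear_predictor = eta,
       converged = converged, separation = separation,
       log_likelihood = ll, dropped = setdiff(seq_len(ncol(X)), keep))
}

#' Combine markers into a single diagnostic score
#'
#' Fits a binary logistic model of class on the marker matrix by
#' iteratively reweighted least squares (at most 50 iterations,
#' convergence when the log-likelihood changes by less than 1e-8;
#' complete separation and rank-deficient designs are detected and
#' reported) and evaluates the fitted linear predictor as a combined
#' marker via [roc_auc()] and [optimal_cutoff_confusion()].
#'
#' @param features numeric matrix or data.frame, subjects by markers
#'   (at least 2 columns).
#' @param labels,positive as in [roc_auc()].
#' @param seed integer seed for the AUC bootstrap CI.
#' @param n_boot bootstrap resamples.
#' @return List with `score` (the linear predictor), `coefficients`
#'   (including intercept; NA for aliased columns), `converged`,
#'   `separation`, `roc` (from [roc_auc()]) and `report` (from
#'   [optimal_cutoff_confusion()]).
#' @export
combine_markers <- function(features, labels, positive = TRUE, seed = 1L,
                            n_boot = 2000) {
  X <- as.matrix(features)
  if (ncol(X) < 2L) stop("need at least 2 markers to combine")
  y <- .binary_labels(labels, positive)
  if (!any(y) || all(y)) stop("both classes must be present")
  stopifnot(nrow(X) == length(y))
  design <- cbind(`(Intercept)` = 1, X)
  fit <- .irls_logistic(design, as.numeric(y))
  score <- fit$linear_predictor
  roc <- roc_auc(score, y, n_boot = n_boot, seed = seed)
  report <- optimal_cutoff_confusion(score, y)
  list(score = score, coefficients = fit$coefficients,
       converged = fit$converged, separation = fit$separation,
       roc = roc, report = report)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return List with `r` and `pval` (t reference with n - 2 degrees of
#'   freedom).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pval = ct$p.value)
}

#' Estimate a per-group zero-inflated log-normal spec from data
#'
#' Moment fit used to feed [kw_power_simulation()] with parameters
#' matching an observed cohort: per group, the zero fraction and the
#' log-scale mean/sd of the non-zero abundances.
#'
#' @param values numeric abundances.
#' @param groups group labels.
#' @return data.frame with `group`, `meanlog`, `sdlog`, `zero_p`.
#' @export
estimate_group_spec <- function(values, groups) {
  groups <- factor(groups)
  do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    nz <- v[v > 0]
    if (length(nz) < 2L) stop("group ", g, " has fewer than 2 non-zero values")
    data.frame(group = g, meanlog = mean(log(nz)),
               sdlog = max(stats::sd(log(nz)), 1e-6),
               zero_p = mean(v == 0), stringsAsFactors = FALSE)
  }))
}

#' Simulation-based power for the Kruskal-Wallis test
#'
#' Simulates `n_reps` cohorts from a per-group zero-inflated log-normal
#' specification and reports the fraction in which the Kruskal-Wallis
#' test rejects at `alpha`, with its binomial Monte-Carlo standard
#' error.
#'
#' @param group_spec data.frame with columns `group`, `meanlog`,
#'   `sdlog`, `zero_p` (see [estimate_group_spec()]).
#' @param n_per_group integer vector of group sizes, matching
#'   `group_spec` rows.
#' @param alpha rejection level (default 0.05).
#' @param n_reps simulated cohorts (>= 100).
#' @param seed integer seed.
#' @return List with `power`, `mc_se`, `n_reps`.
#' @export
kw_power_simulation <- function(group_spec, n_per_group, alpha = 0.05,
                                n_reps = 200, seed = 1L) {
  stopifnot(n_reps >= 100, nrow(group_spec) >= 2L,
            length(n_per_group) == nrow(group_spec))
  with_seed(seed, {
    groups <- rep(group_spec$group, times = n_per_group)
    reject <- vapply(seq_len(n_reps), function(rep) {
      v <- unlist(lapply(seq_len(nrow(group_spec)), function(g) {
        x <- stats::rlnorm(n_per_group[g], group_spec$meanlog[g],
                           group_spec$sdlog[g])
        x[stats::runif(n_per_group[g]) < group_spec$zero_p[g]] <- 0
        x
      }))
      kruskal_wallis(v, groups)$pval < alpha
    }, logical(1))
    p <- mean(reject)
    list(power = p, mc_se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
  })
}

#' Evaluate one taxon as a diagnostic biomarker in a cohort
#'
#' Reproduces the case-control evaluation stage for a single taxon:
#' Kruskal-Wallis across the three groups with eta-squared effect size
#' and simulated power (at the moment-fitted group parameters), ROC/AUC
#' with bootstrap CI, Youden cutoff with confusion-matrix summaries for
#' the positive-versus-reference contrast, and Pearson correlation of
#' abundance with MMSE.
#'
#' @param cohort an `abundance_cohort` (or data.frame with `group`,
#'   `mmse` and taxon columns).
#' @param taxon column name of the taxon to evaluate.
#' @param positive_group,reference_group groups contrasted in the ROC
#'   analysis (defaults PDD vs HC).
#' @param seed integer seed for bootstrap and power simulation.
#' @param n_power_reps replicates for the power simulation.
#' @param n_boot bootstrap resamples for the AUC CI.
#' @return One-row data.frame: `taxon`, `H`, `df`, `pval`,
#'   `p_bonferroni` (across the cohort's taxa), `p_fdr`, `eta2_h`,
#'   `power`, `auc`, `auc_lo`, `auc_hi`, `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `pearson_r_mmse`, `pearson_p`.
#' @export
evaluate_biomarker <- function(cohort, taxon, positive_group = "PDD",
                               reference_group = "HC", seed = 1L,
                               n_power_reps = 200, n_boot = 2000) {
  meta <- c("subject_id", "group", "mmse")
  taxa_cols <- setdiff(names(cohort), meta)
  stopifnot(taxon %in% taxa_cols)
  kw_all <- lapply(taxa_cols, function(tx) {
    kruskal_wallis(cohort[[tx]], cohort$group)
  })
  pvals <- vapply(kw_all, `[[`, numeric(1), "pval")
  idx <- match(taxon, taxa_cols)
  kw <- kw_all[[idx]]
  k <- nlevels(droplevels(factor(cohort$group)))
  eta2 <- eta_squared_h(kw$statistic, k, nrow(cohort))
  spec <- estimate_group_spec(cohort[[taxon]], cohort$group)
  pw <- kw_power_simulation(spec, as.integer(table(cohort$group)),
                            n_reps = n_power_reps, seed = seed)
  sub <- cohort$group %in% c(positive_group, reference_group)
  scores <- cohort[[taxon]][sub]
  y <- cohort$group[sub] == positive_group
  roc <- roc_auc(scores, y, n_boot = n_boot, seed = seed + 1L)
  rep_ <- optimal_cutoff_confusion(scores, y)
  pr <- pearson_r(cohort[[taxon]], cohort$mmse)
  data.frame(
    taxon = taxon, H = kw$statistic, df = kw$df, pval = kw$pval,
    p_bonferroni = adjust_pvalues(pvals, "bonferroni")[idx],
    p_fdr = adjust_pvalues(pvals, "bh_fdr")[idx],
    eta2_h = eta2, power = pw$power, auc = roc$auc,
    auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
    cutoff = rep_$cutoff, sensitivity = rep_$sensitivity,
    specificity = rep_$specificity, accuracy = rep_$accuracy,
    pearson_r_mmse = pr$r, pearson_p = pr$pval,
    stringsAsFactors = FALSE
  )
}
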