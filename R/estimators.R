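# Two-sample MR estimators: Wald ratio, IVW, MR-Egger, weighted median,
# simple and weighted mode.

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

.mr_estimate <- function(method, beta, se, pval, n_snp, extra = list()) {
  structure(list(
    method = method, beta = beta, se = se, pval = pval,
    or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se), n_snp = n_snp, extra = extra
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta=%.4f se=%.4f p=%.3g OR=%.4f (%.4f-%.4f) nSNP=%d\n",
              x$method, x$beta, x$se, x$pval, x$or_, x$ci_low, x$ci_high,
              x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, or_ = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

#' Per-variant Wald ratio
#'
#' The per-instrument causal estimate: outcome effect divided by exposure
#' effect, with the first-order standard error `se_out / |beta_exp|`
#' (exposure-side noise ignored; the weak-instrument filter keeps it
#' small relative to the effect).
#'
#' @param beta_exp,se_exp exposure effect and standard error.
#' @param beta_out,se_out outcome effect and standard error.
#' @return List with numeric vectors `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop("null instrument: beta_exp = 0")
  list(ratio = beta_out / beta_exp, se = se_out / abs(beta_exp))
}

.wald <- function(hset) {
  wald_ratio(hset$beta_exp, hset$se_exp, hset$beta_out, hset$se_out)
}

#' Inverse-variance-weighted estimate
#'
#' The primary two-sample MR estimator: the inverse-variance-weighted
#' mean of the per-variant Wald ratios. The multiplicative
#' random-effects variant (default) inflates the fixed-effect standard
#' error by `max(1, sqrt(Q / (J - 1)))`, where Q is Cochran's
#' heterogeneity statistic; the inflation never deflates below the
#' fixed-effect value.
#'
#' @param hset a `harmonized_set` with at least 2 instruments.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw"`; `extra` carries `q`,
#'   `q_df` and the fixed-effect `se_fixed`.
#' @export
mr_ivw <- function(hset, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  j <- n_instruments(hset)
  if (j < 2L) stop("IVW requires at least 2 instruments")
  wr <- .wald(hset)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  se <- if (model == "fixed") se_fixed else {
    se_fixed * max(1, sqrt(q / (j - 1)))
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("ivw", beta, se, pval, j,
               extra = list(model = model, q = q, q_df = j - 1L,
                            se_fixed = se_fixed))
}

# Weighted least squares of y on x with intercept; returns coefficients,
# their unscaled covariance and the weighted RSS.
.wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swx2 - swx^2
  if (det <= 0) stop("degenerate regression design")
  b1 <- (sw * swxy - swx * swy) / det
  b0 <- (swy - b1 * swx) / sw
  rss <- sum(w * (y - b0 - b1 * x)^2)
  # (X'WX)^{-1}
  vcov <- matrix(c(swx2, -swx, -swx, sw), 2L) / det
  list(intercept = b0, slope = b1, rss = rss, vcov = vcov)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome effects on the
#' exposure effects with an intercept, weights `1/se_out^2`, after
#' re-signing each instrument so its exposure effect is non-negative.
#' The slope is the causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy. Standard errors are inflated by
#' `max(1, sqrt(RSS / (J - 2)))` and p-values use a t reference with
#' `J - 2` degrees of freedom.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @return An `mr_estimate` with method `"mr_egger"`; `extra` carries
#'   `intercept`, `intercept_se` and `intercept_p`.
#' @export
mr_egger <- function(hset) {
  j <- n_instruments(hset)
  if (j < 3L) stop("MR-Egger requires at least 3 instruments")
  sgn <- ifelse(hset$beta_exp < 0, -1, 1)
  x <- sgn * hset$beta_exp
  y <- sgn * hset$beta_out
  w <- 1 / hset$se_out^2
  fit <- .wls(x, y, w)
  infl <- max(1, sqrt(fit$rss / (j - 2)))
  se_int <- infl * sqrt(fit$vcov[1, 1])    # [1,1]: intercept, [2,2]: slope
  se_slope <- infl * sqrt(fit$vcov[2, 2])
  p_slope <- 2 * stats::pt(-abs(fit$slope / se_slope), df = j - 2)
  p_int <- 2 * stats::pt(-abs(fit$intercept / se_int), df = j - 2)
  .mr_estimate("mr_egger", fit$slope, se_slope, p_slope, j,
               extra = list(intercept = fit$intercept, intercept_se = se_int,
                            intercept_p = p_int))
}

# Weighted median of x with weights w: linear interpolation of the sorted
# values at centered cumulative weight 0.5.
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap over per-variant effects; recomputes `estimator`
# (a function of ratio, ratio_se) on each resample and returns the SD.
.boot_se <- function(hset, estimator, n_boot, seed) {
  with_seed(seed, {
    j <- n_instruments(hset)
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bx <- stats::rnorm(j, hset$beta_exp, hset$se_exp)
      by <- stats::rnorm(j, hset$beta_out, hset$se_out)
      bx[bx == 0] <- .Machine$double.eps
      est[b] <- estimator(by / bx, hset$se_out / abs(bx))
    }
    stats::sd(est)
  })
}

#' Weighted-median estimate
#'
#' The weighted median of the per-variant Wald ratios with
#' inverse-variance weights; consistent when instruments carrying at
#' least half of the total weight are valid. The standard error comes
#' from a seeded parametric bootstrap that redraws both effect arrays
#' from their sampling distributions.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1L) {
  j <- n_instruments(hset)
  if (j < 3L) stop("weighted median requires at least 3 instruments")
  wr <- .wald(hset)
  beta <- .weighted_median(wr$ratio, 1 / wr$se^2)
  se <- .boot_se(hset, function(r, s) .weighted_median(r, 1 / s^2),
                 n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("weighted_median", beta, se, pval, j,
               extra = list(n_boot = n_boot))
}

# Kernel-density mode of ratios with weights summing to 1. Bandwidth is
# the modified Silverman rule over the ratios, scaled by phi.
.kde_mode <- function(ratio, w, phi) {
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.349
  a <- min(s, if (iqr > 0) iqr else s)
  h <- phi * 0.9 * a * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratio[1])  # all ratios identical
  d <- stats::density(ratio, weights = w / sum(w), bw = h, n = 2048,
                      kernel = "gaussian")
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the kernel-smoothed density of the per-variant Wald
#' ratios; consistent when the largest group of instruments sharing the
#' same ratio is valid. The simple variant weights ratios equally, the
#' weighted variant by normalized inverse ratio-variance. Bandwidth is
#' `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`.
#'
#' @param hset a `harmonized_set` with at least 3 instruments.
#' @param weighted use inverse-variance weights (default FALSE).
#' @param phi bandwidth scale factor (default 1).
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(hset, weighted = FALSE, phi = 1, n_boot = 1000,
                    seed = 1L) {
  j <- n_instruments(hset)
  if (j < 3L) stop("mode estimator requires at least 3 instruments")
  wr <- .wald(hset)
  wfun <- if (weighted) function(s) 1 / s^2 else function(s) rep(1, length(s))
  beta <- .kde_mode(wr$ratio, wfun(wr$se), phi)
  se <- .boot_se(hset, function(r, s) .kde_mode(r, wfun(s), phi),
                 n_boot, seed)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
               beta, se, pval, j, extra = list(phi = phi, n_boot = n_boot))
}

.MR_METHOD_ORDER <- c("ivw", "mr_egger", "weighted_median", "simple_mode",
                      "weighted_mode")

#' Run all applicable MR estimators
#'
#' With 3 or more instruments, runs the five estimators (IVW, MR-Egger,
#' weighted median, simple mode, weighted mode) in canonical order. With
#' exactly 2 instruments only IVW applies; with 1 the single Wald ratio
#' is reported. Output is deterministic given `seed`.
#'
#' @param hset a `harmonized_set`.
#' @param seed integer seed for bootstrap standard errors.
#' @param n_boot bootstrap replicates per bootstrap-based method.
#' @param ivw_model IVW variant, see [mr_ivw()].
#' @return A data.frame with one row per method: `method`, `n_snp`,
#'   `beta`, `se`, `pval`, `or_`, `ci_low`, `ci_high`, plus
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p` on the
#'   MR-Egger row. An attribute `"note"` records methods skipped for
#'   insufficient instruments.
#' @export
mr_estimate_all <- function(hset, seed = 1L, n_boot = 1000,
                            ivw_model = c("multiplicative_random", "fixed")) {
  ivw_model <- match.arg(ivw_model)
  j <- n_instruments(hset)
  if (j == 0L) stop("no instruments in harmonized set")
  ests <- list()
  note <- character(0)
  if (j == 1L) {
    wr <- .wald(hset)
    pval <- 2 * stats::pnorm(-abs(wr$ratio / wr$se))
    ests$wald_ratio <- .mr_estimate("wald_ratio", wr$ratio, wr$se, pval, 1L)
    note <- "single instrument: Wald ratio only"
  } else {
    ests$ivw <- mr_ivw(hset, model = ivw_model)
    if (j >= 3L) {
      ests$mr_egger <- mr_egger(hset)
      ests$weighted_median <- mr_weighted_median(hset, n_boot = n_boot,
                                                 seed = seed)
      ests$simple_mode <- mr_mode(hset, weighted = FALSE, n_boot = n_boot,
                                  seed = seed + 1L)
      ests$weighted_mode <- mr_mode(hset, weighted = TRUE, n_boot = n_boot,
                                    seed = seed + 2L)
      ests <- ests[.MR_METHOD_ORDER]
    } else {
      note <- "2 instruments: IVW only"
    }
  }
  out <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(out) <- NULL
  out$egger_intercept <- NA_real_
  out$egger_intercept_se <- NA_real_
  out$egger_intercept_p <- NA_real_
  if (!is.null(ests$mr_egger)) {
    k <- which(out$method == "mr_egger")
    out$egger_intercept[k] <- ests$mr_egger$extra$intercept
    out$egger_intercept_se[k] <- ests$mr_egger$extra$intercept_se
    out$egger_intercept_p[k] <- ests$mr_egger$extra$intercept_p
  }
  attr(out, "note") <- note
  out
}

#' Classify the causal signal across methods
#'
#' A causal relationship is called when the IVW estimate is significant
#' at p < 0.05 and every reported method agrees on the direction of
#' effect; a significant IVW with disagreeing directions is flagged as
#' inconsistent; otherwise the result is null.
#'
#' @param estimates the data.frame returned by [mr_estimate_all()], which
#'   must contain an `ivw` row.
#' @param alpha significance level for the IVW p-value (default 0.05).
#' @return One of `"significant_consistent"`,
#'   `"significant_inconsistent"`, `"null"`.
#' @export
classify_causal_signal <- function(estimates, alpha = 0.05) {
  k <- which(estimates$method == "ivw")
  if (!length(k)) stop("no IVW estimate present")
  if (estimates$pval[k] >= alpha) return("null")
  signs <- sign(estimates$beta)
  if (all(signs == signs[k])) "significant_consistent"
  else "significant_inconsistent"
}
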