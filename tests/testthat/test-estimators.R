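test_that("wald_ratio follows its definition and sign symmetry", {
  wr <- wald_ratio(0.1, 0.02, 0.2, 0.05)
  expect_equal(wr$ratio, 2.0)
  expect_equal(wr$se, 0.5)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.05)$ratio, 0)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.05)$se, 0.5)
  neg <- wald_ratio(-0.1, 0.02, -0.2, 0.05)
  expect_equal(neg$ratio, 2.0)
  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "null instrument")
})

test_that("IVW equals the weighted-mean oracle and degenerates cleanly", {
  # ratios/SEs (2.0, 0.5), (1.0, 1.0), (3.0, 0.25): weights 4, 1, 16
  hs <- make_hset(beta_exp = c(1, 1, 1), se_exp = rep(0.01, 3),
                  beta_out = c(2, 1, 3), se_out = c(0.5, 1, 0.25))
  est <- mr_ivw(hs, model = "fixed")
  expect_equal(est$beta, 57 / 21, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 21), tolerance = 1e-12)
  orc <- oracle_ivw(hs$beta_exp, hs$se_exp, hs$beta_out, hs$se_out)
  expect_equal(est$beta, orc$beta, tolerance = 1e-12)
  expect_equal(est$extra$q, orc$q, tolerance = 1e-12)
  # consensus ratios: beta = b, Q = 0, fixed se = (sum w)^(-1/2)
  hs2 <- make_hset(c(0.5, 1, 2), rep(0.01, 3), c(0.35, 0.7, 1.4),
                   c(0.1, 0.2, 0.3))
  est2 <- mr_ivw(hs2, model = "fixed")
  expect_equal(est2$beta, 0.7, tolerance = 1e-12)
  expect_equal(est2$extra$q, 0, tolerance = 1e-12)
  w <- (hs2$beta_exp / hs2$se_out)^2
  expect_equal(est2$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_error(mr_ivw(make_hset(1, 0.1, 1, 0.1)), "at least 2")
})

test_that("IVW fixed effect equals the intercept-free WLS slope", {
  set.seed(21)
  hs <- make_hset(rnorm(15, 0.1, 0.02), runif(15, 0.005, 0.02),
                  rnorm(15, 0.05, 0.05), runif(15, 0.02, 0.1))
  est <- mr_ivw(hs, model = "fixed")
  w <- 1 / hs$se_out^2
  slope <- sum(w * hs$beta_exp * hs$beta_out) / sum(w * hs$beta_exp^2)
  expect_equal(est$beta, slope, tolerance = 1e-12)
})

test_that("random-effects IVW never deflates below the fixed-effect SE", {
  set.seed(22)
  hs <- make_hset(rnorm(10, 0.1, 0.02), runif(10, 0.005, 0.02),
                  rnorm(10, 0.03, 0.08), runif(10, 0.02, 0.1))
  expect_gte(mr_ivw(hs)$se, mr_ivw(hs, model = "fixed")$se)
  # homogeneous data: the floor binds and the two variants coincide
  hs2 <- make_hset(c(0.5, 1, 2), rep(0.01, 3), c(0.35, 0.7, 1.4),
                   c(0.1, 0.2, 0.3))
  expect_equal(mr_ivw(hs2)$se, mr_ivw(hs2, model = "fixed")$se)
})

test_that("MR-Egger interpolates exact linear data and matches lm", {
  # exact line beta_out = 0.05 + 0.8 * beta_exp, no noise
  x <- c(0.05, 0.1, 0.15, 0.2)
  hs <- make_hset(x, rep(0.01, 4), 0.05 + 0.8 * x, rep(0.05, 4))
  est <- mr_egger(hs)
  expect_equal(est$beta, 0.8, tolerance = 1e-10)
  expect_equal(est$extra$intercept, 0.05, tolerance = 1e-10)
  # noisy 4-point fixture against the weighted-lm oracle
  set.seed(7)
  hs2 <- make_hset(c(0.05, 0.08, 0.12, 0.2), rep(0.01, 4),
                   c(0.06, 0.02, 0.11, 0.13), c(0.04, 0.05, 0.03, 0.06))
  est2 <- mr_egger(hs2)
  w <- 1 / hs2$se_out^2
  fit <- lm(hs2$beta_out ~ hs2$beta_exp, weights = w)
  expect_equal(est2$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(est2$extra$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # SEs: lm's sigma, but floored at 1
  sm <- summary(fit)
  infl <- max(1, sm$sigma) / sm$sigma
  expect_equal(est2$se, unname(sm$coefficients[2, 2]) * infl,
               tolerance = 1e-10)
  expect_equal(est2$extra$intercept_se,
               unname(sm$coefficients[1, 2]) * infl, tolerance = 1e-10)
  expect_error(mr_egger(make_hset(c(1, 1), c(0.1, 0.1), c(1, 1),
                                  c(0.1, 0.1))), "at least 3")
})

test_that("MR-Egger re-signs instruments to non-negative exposure effects", {
  x <- c(0.05, 0.1, 0.15, 0.2)
  y <- 0.05 + 0.8 * x
  hs <- make_hset(x, rep(0.01, 4), y, rep(0.05, 4))
  flip <- c(-1, 1, -1, 1)
  hs2 <- make_hset(flip * x, rep(0.01, 4), flip * y, rep(0.05, 4))
  e1 <- mr_egger(hs); e2 <- mr_egger(hs2)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$extra$intercept, e2$extra$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative-weight walk", {
  # equal weights, ratios {1,2,3}: plain median
  hs <- make_hset(c(1, 1, 1), rep(0.01, 3), c(1, 2, 3), rep(0.5, 3))
  expect_equal(mr_weighted_median(hs, n_boot = 50, seed = 1)$beta, 2.0)
  # >50% of the weight on one ratio pins the estimate there
  hs2 <- make_hset(c(1, 1, 1), rep(0.01, 3), c(1, 2, 10),
                   c(1, 0.1, 1))  # weights 1, 100, 1
  expect_equal(mr_weighted_median(hs2, n_boot = 50, seed = 1)$beta, 2.0)
  # 5-instrument fixture: manual interpolation oracle
  ratios <- c(0.8, 1.0, 1.4, 2.0, 3.0)
  ses <- c(0.5, 0.25, 0.5, 1.0, 0.25)
  hs3 <- make_hset(rep(1, 5), rep(0.01, 5), ratios, ses)
  w <- 1 / ses^2                       # 4, 16, 4, 1, 16
  p <- (cumsum(w) - 0.5 * w) / sum(w)  # centered cumulative weights
  # 0.5 falls between p[2] and p[3]; linear interpolation by hand
  k <- max(which(p < 0.5))
  manual <- ratios[k] + (ratios[k + 1] - ratios[k]) *
    (0.5 - p[k]) / (p[k + 1] - p[k])
  expect_equal(mr_weighted_median(hs3, n_boot = 50, seed = 1)$beta, manual,
               tolerance = 1e-6)
})

test_that("mode estimators find the dominant ratio cluster", {
  # all ratios identical: returned exactly
  hs <- make_hset(c(1, 1, 1), rep(0.01, 3), c(2, 2, 2), rep(0.5, 3))
  expect_equal(mr_mode(hs, n_boot = 50, seed = 1)$beta, 2.0)
  # 4 ratios near 1 plus an outlier at 10: mode near 1, not the mean
  hs2 <- make_hset(rep(1, 5), rep(0.01, 5), c(0.95, 1.0, 1.05, 1.1, 10),
                   rep(0.5, 5))
  m <- mr_mode(hs2, n_boot = 50, seed = 1)$beta
  expect_lt(abs(m - 1.02), 0.2)
  # density-grid oracle: manual weighted gaussian KDE argmax
  r <- c(0.95, 1.0, 1.05, 1.1, 10)
  s <- sd(r); iqr <- IQR(r) / 1.349
  h <- 0.9 * min(s, iqr) * 5^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(g) mean(dnorm((g - r) / h)), numeric(1))
  expect_lt(abs(m - grid[which.max(dens)]), 0.01)
  # equal weights: weighted and simple modes coincide
  hs3 <- make_hset(rep(1, 4), rep(0.01, 4), c(1, 1.2, 1.3, 2), rep(0.5, 4))
  expect_equal(mr_mode(hs3, weighted = TRUE, n_boot = 50, seed = 1)$beta,
               mr_mode(hs3, weighted = FALSE, n_boot = 50, seed = 1)$beta)
})

test_that("mr_estimate_all returns methods in canonical order by arity", {
  sim <- simulate_summary_stats(simulation_truth(beta_causal = 0.3,
                                                 j_snps = 10, seed = 3))
  hs <- harmonize(sim$exposure, sim$outcome)
  est <- mr_estimate_all(hs, seed = 1, n_boot = 100)
  expect_identical(est$method, c("ivw", "mr_egger", "weighted_median",
                                 "simple_mode", "weighted_mode"))
  expect_true(all(est$ci_low <= est$or_ & est$or_ <= est$ci_high))
  # two instruments: IVW only
  hs2 <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                   c(0.02, 0.02))
  est2 <- mr_estimate_all(hs2)
  expect_identical(est2$method, "ivw")
  # determinism given the seed
  est_b <- mr_estimate_all(hs, seed = 1, n_boot = 100)
  expect_identical(est, est_b)
})

test_that("estimators are sign- and scale-equivariant", {
  sim <- simulate_summary_stats(simulation_truth(beta_causal = 0.25,
                                                 j_snps = 12, seed = 8))
  hs <- harmonize(sim$exposure, sim$outcome)
  neg <- hs; neg$beta_out <- -hs$beta_out
  scl <- hs; scl$beta_exp <- 2 * hs$beta_exp
  base <- mr_estimate_all(hs, seed = 4, n_boot = 100)
  flip <- mr_estimate_all(neg, seed = 4, n_boot = 100)
  half <- mr_estimate_all(scl, seed = 4, n_boot = 100)
  expect_equal(flip$beta, -base$beta, tolerance = 1e-8)
  expect_equal(half$beta, base$beta / 2, tolerance = 1e-8)
})

test_that("the significance rule combines IVW p and directional agreement", {
  mk <- function(p_ivw, betas) {
    data.frame(method = c("ivw", "mr_egger", "weighted_median"),
               beta = betas, se = 0.1,
               pval = c(p_ivw, 0.5, 0.5))
  }
  expect_identical(classify_causal_signal(mk(0.004, c(0.5, 0.4, 0.6))),
                   "significant_consistent")
  expect_identical(classify_causal_signal(mk(0.2, c(0.5, 0.4, 0.6))),
                   "null")
  expect_identical(classify_causal_signal(mk(0.01, c(0.5, -0.1, 0.6))),
                   "significant_inconsistent")
  expect_error(classify_causal_signal(data.frame(method = "mr_egger",
                                                 beta = 1, pval = 0.01)),
               "no IVW")
})
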