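test_that("Kruskal-Wallis matches the rank-formula oracle", {
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  expect_equal(kw$pval, pchisq(7.2, 2, lower.tail = FALSE))
  # all values tied: no evidence
  kw0 <- kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$pval, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(41)
  v <- rlnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(log(v), g)$statistic, tolerance = 1e-12)
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(rank(v), g)$statistic, tolerance = 1e-12)
})

test_that("eta-squared follows (H - k + 1)/(n - k)", {
  expect_equal(eta_squared_h(2, 3, 100), 0)       # null expectation H = k-1
  expect_equal(eta_squared_h(7.2, 3, 9), 5.2 / 6)
  expect_error(eta_squared_h(5, 3, 3), "exceed")
})

test_that("multiplicity adjustments match hand computations", {
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bh_fdr"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh_fdr"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.004, 3), "bonferroni")[1], 0.012)
  set.seed(42)
  p <- runif(20)
  bf <- adjust_pvalues(p, "bonferroni")
  bh <- adjust_pvalues(p, "bh_fdr")
  expect_true(all(bf >= p) && all(bh >= p))  # never decreases
  expect_true(all(bf >= bh))                 # Bonferroni dominates BH
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("AUC equals the brute-force concordant-pair count", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.5, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
              FALSE)
  pairs <- expand.grid(p = which(labels), n = which(!labels))
  oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                        ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, oracle, tolerance = 1e-12)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE,
                                           FALSE))$auc, 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC is antisymmetric under score negation and matches pROC", {
  set.seed(43)
  scores <- round(rnorm(40), 1)  # ties on purpose
  labels <- rep(c(TRUE, FALSE), 20)
  a1 <- roc_auc(scores, labels)$auc
  a2 <- roc_auc(-scores, labels)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
  expect_equal(a1, as.numeric(ref), tolerance = 1e-12)
})

test_that("the AUC bootstrap CI is seeded and covers the estimate", {
  set.seed(44)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  r1 <- roc_auc(scores, labels, n_boot = 400, seed = 3)
  r2 <- roc_auc(scores, labels, n_boot = 400, seed = 3)
  expect_identical(r1$auc_ci, r2$auc_ci)
  expect_true(r1$auc_ci[1] <= r1$auc && r1$auc <= r1$auc_ci[2])
})

test_that("the Youden cutoff matches an exhaustive sweep", {
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.6, 0.8)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  rep_ <- optimal_cutoff_confusion(scores, labels)
  # brute-force sweep over all candidate cutoffs (risk direction)
  best <- -Inf; best_cut <- NA
  for (cut in sort(unique(scores))) {
    p <- scores >= cut
    j <- mean(p[labels]) + mean(!p[!labels]) - 1
    if (j > best) { best <- j; best_cut <- cut }
  }
  expect_equal(rep_$cutoff, best_cut)
  expect_equal(rep_$youden_j, best)
  expect_equal(sum(rep_$confusion), 6L)
  expect_equal(rep_$accuracy,
               (rep_$confusion[1, 1] + rep_$confusion[2, 2]) / 6)
  # perfect separation: everything is 1
  perf <- optimal_cutoff_confusion(c(5, 6, 7, 1, 2),
                                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$accuracy, 1)
  # constant scores degenerate with a warning
  expect_warning(deg <- optimal_cutoff_confusion(rep(1, 6), labels),
                 "constant")
  expect_true(deg$degenerate)
  expect_equal(deg$youden_j, 0)
})

test_that("protective markers are auto-detected and thresholded <=", {
  scores <- c(5, 6, 7, 1, 2)            # high score = healthy
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  rep_ <- optimal_cutoff_confusion(scores, labels)
  expect_identical(rep_$direction, "protective")
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
})

test_that("confusion-matrix identities hold on random fixtures", {
  set.seed(45)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    r <- suppressWarnings(optimal_cutoff_confusion(scores, labels))
    cm <- r$confusion
    expect_equal(sum(cm), n)
    expect_equal(r$accuracy, (cm[1, 1] + cm[2, 2]) / n)
    expect_equal(r$sensitivity, cm[1, 1] / (cm[1, 1] + cm[2, 1]))
    expect_equal(r$specificity, cm[2, 2] / (cm[2, 2] + cm[1, 2]))
  }
})

test_that("the in-module logistic fit matches glm on a small fixture", {
  x1 <- c(0.2, 0.5, 0.1, 0.9, 0.8, 0.3, 0.7, 0.4)
  x2 <- c(1.0, 0.2, 0.8, 0.3, 0.9, 0.6, 0.1, 0.5)
  y <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  cm <- combine_markers(cbind(m1 = x1, m2 = x2), y, seed = 1, n_boot = 100)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(cm$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_true(cm$converged)
})

test_that("a duplicated marker changes nothing and noise cannot hurt much", {
  set.seed(46)
  x <- c(rnorm(25, 1), rnorm(25))
  y <- rep(c(TRUE, FALSE), each = 25)
  single_auc <- roc_auc(x, y)$auc
  dup <- combine_markers(cbind(a = x, b = x), y, seed = 2, n_boot = 100)
  expect_equal(dup$roc$auc, single_auc, tolerance = 1e-12)
  expect_true(any(is.na(dup$coefficients)))  # aliased column dropped
  noise <- rnorm(50)
  both <- combine_markers(cbind(a = x, z = noise), y, seed = 2,
                          n_boot = 100)
  expect_gte(both$roc$auc, single_auc - 0.05)
})

test_that("complete separation is detected and still usable for ranking", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  cm <- suppressWarnings(combine_markers(cbind(a = x, b = x + rnorm(6, 0, 1e-4)),
                                         y, seed = 3, n_boot = 50))
  expect_equal(cm$roc$auc, 1)
  expect_true(cm$separation || cm$converged)
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2.1, 1.9, 3.5, 3.2, 5.0, 4.4)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pr <- pearson_r(x, y)
  expect_equal(pr$r, hand, tolerance = 1e-12)
  tstat <- hand * sqrt(4 / (1 - hand^2))
  expect_equal(pr$pval, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 6)), "zero variance")
})

test_that("simulated power is near alpha under the null, near 1 far away", {
  null_spec <- data.frame(group = c("a", "b", "c"), meanlog = -6,
                          sdlog = 0.9, zero_p = 0.1)
  pw0 <- kw_power_simulation(null_spec, c(25, 25, 25), n_reps = 400,
                             seed = 1)
  expect_lt(abs(pw0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 1e-9)
  big_spec <- data.frame(group = c("a", "b", "c"),
                         meanlog = c(-8, -6, -4), sdlog = 0.3,
                         zero_p = 0)
  pw1 <- kw_power_simulation(big_spec, c(25, 25, 25), n_reps = 150,
                             seed = 1)
  expect_gt(pw1$power, 0.99)
  # reproducibility
  expect_identical(kw_power_simulation(null_spec, c(25, 25, 25),
                                       n_reps = 120, seed = 9)$power,
                   kw_power_simulation(null_spec, c(25, 25, 25),
                                       n_reps = 120, seed = 9)$power)
})

test_that("evaluate_biomarker assembles a coherent single-taxon report", {
  coh <- simulate_cohort(seed = 21)
  row <- evaluate_biomarker(coh, "Subdoligranulum", seed = 4,
                            n_power_reps = 120, n_boot = 300)
  expect_equal(nrow(row), 1L)
  expect_gte(row$p_bonferroni, row$pval)
  expect_gte(row$p_fdr, row$pval)
  expect_gte(row$p_bonferroni, row$p_fdr)
  expect_true(row$auc_lo <= row$auc && row$auc <= row$auc_hi)
  expect_true(row$accuracy >= 0 && row$accuracy <= 1)
  expect_equal(row$eta2_h, eta_squared_h(row$H, 3, 75))
  # MMSE correlation mirrors the generator's target direction
  expect_lt(row$pearson_r_mmse, 0)
})
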