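# Shared fixtures and independent oracles.

# A small valid summary-statistics table.
make_table <- function(n = 5, trait_id = "trait", trait_type = "continuous",
                       pval = NULL, seed = 42) {
  set.seed(seed)
  summary_stats(data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 100000L,
    effect_allele = "A", other_allele = "G",
    beta = round(stats::rnorm(n, 0, 0.1), 6),
    se = round(stats::runif(n, 0.005, 0.02), 6),
    pval = if (is.null(pval)) round(stats::runif(n, 1e-8, 0.5), 8) else pval,
    eaf = round(stats::runif(n, 0.1, 0.9), 4),
    n = 10000L
  ), trait_id = trait_id, trait_type = trait_type)
}

make_hset <- function(beta_exp, se_exp, beta_out, se_out) {
  harmonized_set(sprintf("rs%03d", seq_along(beta_exp)),
                 beta_exp, se_exp, beta_out, se_out)
}

# Independent fixed-effect IVW oracle on Wald ratios.
oracle_ivw <- function(beta_exp, se_exp, beta_out, se_out) {
  r <- beta_out / beta_exp
  s <- se_out / abs(beta_exp)
  w <- 1 / s^2
  b <- sum(w * r) / sum(w)
  list(beta = b, se = sqrt(1 / sum(w)),
       q = sum(w * (r - b)^2))
}

# Independent greedy clumping oracle over an explicit r2 matrix.
# r2mat: symmetric matrix indexed like the table rows.
oracle_clump <- function(tab, r2mat, r2_threshold, window_kb) {
  ord <- order(tab$pval, tab$chrom, tab$pos, tab$snp)
  alive <- rep(TRUE, nrow(tab))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    for (k in which(alive)) {
      if (tab$chrom[k] == tab$chrom[i] &&
          abs(tab$pos[k] - tab$pos[i]) / 1000 < window_kb &&
          r2mat[i, k] >= r2_threshold) {
        alive[k] <- FALSE
      }
    }
  }
  tab$snp[kept]
}
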