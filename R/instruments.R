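# Instrument selection, LD clumping and allele harmonization.

#' Instrument-strength F-statistic
#'
#' The squared instrument z-score, `(beta/se)^2`. Instruments with
#' F below 10 are conventionally considered weak and excluded.
#'
#' @param beta,se numeric vectors of per-allele effects and standard
#'   errors (`se > 0`).
#' @return Numeric vector of F-statistics (always >= 0).
#' @export
f_statistic <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (any(!is.na(se) & se <= 0)) stop("se must be strictly positive")
  (beta / se)^2
}

#' Select instrumental variables from a summary-statistics table
#'
#' Retains variants with association p-value below `p_threshold` and
#' F-statistic at least `f_min`; row order is preserved.
#'
#' @param table a [summary_stats()] table.
#' @param p_threshold association p-value cutoff (default `1e-5`, the
#'   relaxed genome-wide threshold commonly used for microbiome GWAS).
#' @param f_min minimum instrument F-statistic (default 10).
#' @return The filtered `summary_stats` table.
#' @export
select_instruments <- function(table, p_threshold = 1e-5, f_min = 10) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      is.na(p_threshold) || p_threshold <= 0) {
    stop("p_threshold must be a positive number")
  }
  keep <- table$pval < p_threshold & f_statistic(table$beta, table$se) >= f_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_id", "trait_type")] <-
    attributes(table)[c("trait_id", "trait_type")]
  class(out) <- c("summary_stats", "data.frame")
  out
}

# ---- LD lookup -------------------------------------------------------------

.ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Pairwise LD lookup
#'
#' A symmetric map from variant pairs to squared correlation r2. Pairs
#' absent from the lookup are treated as r2 = 0; the diagonal is 1.
#'
#' @param snp_a,snp_b character vectors of variant identifiers.
#' @param r2 numeric vector of r2 values in `[0, 1]`.
#' @return An `ld_lookup` object.
#' @export
ld_lookup <- function(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0)) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  env <- new.env(parent = emptyenv(), size = max(29L, 2L * length(r2)))
  keys <- .ld_key(as.character(snp_a), as.character(snp_b))
  for (i in seq_along(keys)) assign(keys[i], r2[i], envir = env)
  structure(list(env = env, n_pairs = length(unique(keys))),
            class = "ld_lookup")
}

#' @export
print.ld_lookup <- function(x, ...) {
  cat(sprintf("LD lookup with %d stored pair(s)\n", x$n_pairs))
  invisible(x)
}

#' Query pairwise r2 from an LD lookup
#'
#' @param ld an [ld_lookup()] object.
#' @param a,b character vectors of variant identifiers (recycled).
#' @return Numeric vector of r2 values; 1 when `a == b`, 0 for pairs not
#'   present in the lookup.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_lookup"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  keys <- .ld_key(a, b)
  out <- vapply(keys, function(k) {
    v <- get0(k, envir = ld$env, ifnotfound = NA_real_)
    if (is.na(v)) 0 else v
  }, numeric(1), USE.NAMES = FALSE)
  out[a == b] <- 1
  out
}

#' Read an LD lookup from a tab-separated file
#'
#' Expects a header with columns `snp_a`, `snp_b`, `r2`.
#'
#' @param path file to read.
#' @return An [ld_lookup()] object.
#' @export
read_ld_lookup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("snp_a", "snp_b", "r2")) {
    if (!col %in% names(df)) stop("LD file missing column: ", col)
  }
  ld_lookup(df$snp_a, df$snp_b, as.numeric(df$r2))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest p-value as an
#' index and removes all unclaimed variants on the same chromosome whose
#' center-to-center distance is below `window_kb` and whose r2 with the
#' index is at least `r2_threshold`. Ties in p-value are broken by
#' (chromosome, position, identifier). The surviving indices are returned
#' sorted by p-value ascending.
#'
#' @param table a [summary_stats()] table carrying `chrom` and `pos`.
#' @param ld an [ld_lookup()] object.
#' @param r2_threshold r2 at or above which variants are claimed by an
#'   index (default 0.01).
#' @param window_kb clumping window in kilobases, measured
#'   center-to-center (default 10000).
#' @return The clumped `summary_stats` table, ordered by p-value.
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.01, window_kb = 10000) {
  stopifnot(inherits(ld, "ld_lookup"))
  n <- nrow(table)
  if (n == 0L) return(table)
  if (any(is.na(table$chrom)) || any(is.na(table$pos))) {
    stop("ld_clump requires chrom and pos on every record")
  }
  ord <- order(table$pval, table$chrom, table$pos, table$snp)
  unclaimed <- rep(TRUE, n)
  kept <- integer(0)
  for (i in ord) {
    if (!unclaimed[i]) next
    unclaimed[i] <- FALSE
    kept <- c(kept, i)
    cand <- which(unclaimed & table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) / 1000 < window_kb)
    if (length(cand)) {
      r2 <- ld_r2(ld, table$snp[i], table$snp[cand])
      unclaimed[cand[r2 >= r2_threshold]] <- FALSE
    }
  }
  out <- table[kept, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_id", "trait_type")] <-
    attributes(table)[c("trait_id", "trait_type")]
  class(out) <- c("summary_stats", "data.frame")
  out
}

# ---- Harmonization ---------------------------------------------------------

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(ea, oa) unname(.complement[ea] == oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table onto the exposure's effect-allele
#' orientation over the shared variants. Outcome records whose alleles
#' are swapped have their effect sign negated and frequency complemented;
#' strand-complement matches are resolved by complementing first.
#' Palindromic variants (A/T or G/C) cannot be strand-resolved from
#' alleles: they are oriented by effect-allele-frequency agreement when
#' both frequencies are available and fall outside the ambiguity band,
#' and dropped otherwise. Incompatible allele pairs are dropped.
#'
#' @param exposure,outcome [summary_stats()] tables.
#' @param palindrome_eaf_band palindromic variants with either frequency
#'   in `[band, 1 - band]` are dropped as ambiguous (default 0.42, i.e.
#'   frequencies within 0.42-0.58).
#' @return A `harmonized_set`: list with `snp`, aligned `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, trait ids, and
#'   `actions`, a per-variant record over all exposure instruments with
#'   values `kept`, `flipped`, `dropped_palindromic`,
#'   `dropped_incompatible` or `dropped_missing`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_band = 0.42) {
  if (palindrome_eaf_band < 0 || palindrome_eaf_band > 0.5) {
    stop("palindrome_eaf_band must lie in [0, 0.5]")
  }
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) stop("no shared instruments")
  actions <- stats::setNames(rep("dropped_missing", nrow(exposure)),
                             exposure$snp)
  oidx <- match(exposure$snp, outcome$snp)
  keep_rows <- list()
  for (i in seq_len(nrow(exposure))) {
    j <- oidx[i]
    if (is.na(j)) next
    e_ea <- exposure$effect_allele[i]; e_oa <- exposure$other_allele[i]
    o_ea <- outcome$effect_allele[j]; o_oa <- outcome$other_allele[j]
    b_out <- outcome$beta[j]; eaf_out <- outcome$eaf[j]
    snp <- exposure$snp[i]
    if (.is_palindromic(e_ea, e_oa)) {
      # outcome must carry the same palindromic pair in either order
      if (!setequal(c(o_ea, o_oa), c(e_ea, e_oa))) {
        actions[snp] <- "dropped_incompatible"
        next
      }
      eaf_exp <- exposure$eaf[i]
      if (is.na(eaf_exp) || is.na(eaf_out)) {
        actions[snp] <- "dropped_palindromic"
        next
      }
      lo <- palindrome_eaf_band; hi <- 1 - palindrome_eaf_band
      if ((eaf_exp >= lo && eaf_exp <= hi) ||
          (eaf_out >= lo && eaf_out <= hi)) {
        actions[snp] <- "dropped_palindromic"
        next
      }
      flipped <- FALSE
      if (o_ea != e_ea) {           # nominal swap by allele letters
        b_out <- -b_out; eaf_out <- 1 - eaf_out; flipped <- !flipped
      }
      if ((eaf_exp - 0.5) * (eaf_out - 0.5) < 0) {  # strand flip implied
        b_out <- -b_out; eaf_out <- 1 - eaf_out; flipped <- !flipped
      }
      actions[snp] <- if (flipped) "flipped" else "kept"
    } else {
      if (o_ea == e_ea && o_oa == e_oa) {
        actions[snp] <- "kept"
      } else if (o_ea == e_oa && o_oa == e_ea) {
        b_out <- -b_out; eaf_out <- 1 - eaf_out
        actions[snp] <- "flipped"
      } else if (.complement[o_ea] == e_ea && .complement[o_oa] == e_oa) {
        actions[snp] <- "kept"      # strand complement only
      } else if (.complement[o_ea] == e_oa && .complement[o_oa] == e_ea) {
        b_out <- -b_out; eaf_out <- 1 - eaf_out
        actions[snp] <- "flipped"
      } else {
        actions[snp] <- "dropped_incompatible"
        next
      }
    }
    keep_rows[[length(keep_rows) + 1L]] <- list(
      snp = snp, beta_exp = exposure$beta[i], se_exp = exposure$se[i],
      beta_out = b_out, se_out = outcome$se[j],
      eaf_exp = exposure$eaf[i], eaf_out = eaf_out
    )
  }
  pull <- function(f) vapply(keep_rows, function(r) r[[f]], numeric(1))
  hs <- structure(list(
    snp = vapply(keep_rows, `[[`, "", "snp"),
    beta_exp = pull("beta_exp"), se_exp = pull("se_exp"),
    beta_out = pull("beta_out"), se_out = pull("se_out"),
    eaf_exp = pull("eaf_exp"), eaf_out = pull("eaf_out"),
    exposure_id = attr(exposure, "trait_id"),
    outcome_id = attr(outcome, "trait_id"),
    actions = actions
  ), class = "harmonized_set")
  hs
}

#' Construct a harmonized set directly from aligned arrays
#'
#' Mostly useful for tests and simulations where the alignment is known.
#'
#' @param snp variant identifiers.
#' @param beta_exp,se_exp,beta_out,se_out aligned effect and standard
#'   error arrays; standard errors strictly positive.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set` object.
#' @export
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           exposure_id = "exposure",
                           outcome_id = "outcome") {
  n <- length(snp)
  stopifnot(length(beta_exp) == n, length(se_exp) == n,
            length(beta_out) == n, length(se_out) == n, n >= 1L)
  if (any(se_exp <= 0) || any(se_out <= 0)) {
    stop("standard errors must be strictly positive")
  }
  structure(list(
    snp = as.character(snp),
    beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
    beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
    eaf_exp = rep(NA_real_, n), eaf_out = rep(NA_real_, n),
    exposure_id = exposure_id, outcome_id = outcome_id,
    actions = stats::setNames(rep("kept", n), snp)
  ), class = "harmonized_set")
}

#' Number of instruments in a harmonized set
#' @param hset a `harmonized_set`.
#' @return Integer count of aligned instruments.
#' @export
n_instruments <- function(hset) length(hset$snp)

#' @export
print.harmonized_set <- function(x, ...) {
  acts <- table(factor(x$actions, levels = c(
    "kept", "flipped", "dropped_palindromic", "dropped_incompatible",
    "dropped_missing")))
  cat(sprintf("Harmonized set: %s -> %s, %d instrument(s)\n",
              x$exposure_id, x$outcome_id, length(x$snp)))
  cat("  actions:", paste(names(acts)[acts > 0], acts[acts > 0],
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
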