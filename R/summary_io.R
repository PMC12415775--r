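# GWAS summary-statistic tables: construction, validation, reading, writing.

.CANONICAL_COLS <- c(snp = "SNP", chrom = "CHR", pos = "POS",
                     effect_allele = "EA", other_allele = "OA",
                     beta = "BETA", se = "SE", pval = "P",
                     eaf = "EAF", n = "N")
.MANDATORY <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
.VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics table
#'
#' One row per variant: identifier, chromosome, 1-based position, effect
#' and other allele, per-effect-allele effect size (log odds ratio for a
#' binary trait), its standard error, p-value, and optionally the
#' effect-allele frequency and sample size.
#'
#' @param df data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`; for binary traits
#'   `beta` is interpreted on the log-odds scale.
#' @param check validate invariants and fail on violation (default TRUE).
#' @return A `summary_stats` object (a data.frame with trait metadata).
#' @export
summary_stats <- function(df, trait_id, trait_type = c("continuous", "binary"),
                          check = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df), is.character(trait_id), length(trait_id) == 1L)
  for (col in .MANDATORY) {
    if (!col %in% names(df)) stop("missing mandatory column: ", col)
  }
  if (!"chrom" %in% names(df)) df$chrom <- NA_character_
  if (!"pos" %in% names(df)) df$pos <- NA_integer_
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_integer_
  df <- df[, names(.CANONICAL_COLS)]
  df$snp <- as.character(df$snp)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$beta <- as.numeric(df$beta)
  df$se <- as.numeric(df$se)
  df$pval <- as.numeric(df$pval)
  df$eaf <- as.numeric(df$eaf)
  df$n <- as.numeric(df$n)
  rownames(df) <- NULL
  obj <- structure(df, trait_id = trait_id, trait_type = trait_type,
                   class = c("summary_stats", "data.frame"))
  if (check) {
    issues <- validate_table(obj)
    if (length(issues)) {
      stop("invalid summary-statistics table:\n  ",
           paste(issues, collapse = "\n  "))
    }
  }
  obj
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Trait metadata accessors
#' @param table a `summary_stats` object.
#' @return character scalar.
#' @export
trait_id <- function(table) attr(table, "trait_id")

#' @rdname trait_id
#' @export
trait_type <- function(table) attr(table, "trait_type")

#' Validate a summary-statistics table
#'
#' Checks every row invariant (distinct single-nucleotide alleles,
#' positive standard error, p-value in (0, 1], frequency in (0, 1) when
#' present) and table-level uniqueness of variant identifiers.
#'
#' @param table a `summary_stats` object or plain data.frame with
#'   canonical columns.
#' @return Character vector of human-readable issues; empty iff the
#'   table satisfies every invariant.
#' @export
validate_table <- function(table) {
  issues <- character(0)
  dup <- unique(table$snp[duplicated(table$snp)])
  for (d in dup) issues <- c(issues, paste0(d, ": duplicate snp_id"))
  bad_allele <- !(table$effect_allele %in% .VALID_ALLELES) |
    !(table$other_allele %in% .VALID_ALLELES)
  same_allele <- !bad_allele & table$effect_allele == table$other_allele
  bad_se <- is.na(table$se) | table$se <= 0
  bad_p <- is.na(table$pval) | table$pval <= 0 | table$pval > 1
  bad_eaf <- !is.na(table$eaf) & (table$eaf <= 0 | table$eaf >= 1)
  bad_beta <- is.na(table$beta) | !is.finite(table$beta)
  flag <- function(mask, what) {
    if (any(mask)) paste0(table$snp[mask], ": ", what) else character(0)
  }
  c(issues,
    flag(bad_allele, "allele outside {A,C,G,T}"),
    flag(same_allele, "effect_allele equals other_allele"),
    flag(bad_se, "se not strictly positive"),
    flag(bad_p, "pval out of range"),
    flag(bad_eaf, "eaf out of range"),
    flag(bad_beta, "beta not finite"))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Parses a tab-separated file with a header row into a [summary_stats()]
#' table. Rows violating the record invariants (non-SNP alleles,
#' non-positive standard errors, out-of-range p-values) are dropped and
#' counted; a p-value of exactly zero is clamped to the smallest positive
#' double with a warning, since downstream steps take -log transforms.
#'
#' @param path file to read.
#' @param column_map named character vector mapping canonical names
#'   (`SNP`, `CHR`, `POS`, `EA`, `OA`, `BETA`, `SE`, `P`, `EAF`, `N`) to
#'   the file's column names; unmapped names use the canonical default.
#' @param trait_id,trait_type trait metadata (see [summary_stats()]).
#' @param sep field separator (default tab).
#' @param quiet suppress the drop-report message.
#' @return A `summary_stats` table with attribute `"drop_report"`, a
#'   named integer vector counting rows dropped per rule.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id,
                               trait_type = c("continuous", "binary"),
                               sep = "\t", quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cmap <- .CANONICAL_COLS
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), unname(.CANONICAL_COLS))
    if (length(unknown)) stop("unknown canonical names in column_map: ",
                              paste(unknown, collapse = ", "))
    cmap[match(names(column_map), cmap)] <- unname(column_map)
  }
  for (field in .MANDATORY) {
    if (!cmap[[field]] %in% names(raw)) {
      stop("mandatory column '", cmap[[field]], "' (", field,
           ") absent from header of ", path)
    }
  }
  get_col <- function(field) {
    cn <- cmap[[field]]
    if (cn %in% names(raw)) raw[[cn]] else rep(NA_character_, nrow(raw))
  }
  df <- data.frame(
    snp = get_col("snp"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pval = suppressWarnings(as.numeric(get_col("pval"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE
  )
  n_zero_p <- sum(!is.na(df$pval) & df$pval == 0)
  if (n_zero_p > 0) {
    warning(n_zero_p, " p-value(s) of exactly 0 clamped to the smallest ",
            "positive double")
    df$pval[!is.na(df$pval) & df$pval == 0] <- .Machine$double.xmin
  }
  drop <- c(
    non_snp_allele = 0L, same_allele = 0L, bad_se = 0L,
    bad_pval = 0L, bad_eaf = 0L, bad_beta = 0L
  )
  keep <- rep(TRUE, nrow(df))
  mark <- function(mask, rule) {
    newly <- mask & keep
    drop[[rule]] <<- sum(newly)
    keep <<- keep & !mask
  }
  mark(!(df$effect_allele %in% .VALID_ALLELES) |
         !(df$other_allele %in% .VALID_ALLELES), "non_snp_allele")
  mark(df$effect_allele == df$other_allele, "same_allele")
  mark(is.na(df$se) | df$se <= 0, "bad_se")
  mark(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "bad_pval")
  mark(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "bad_eaf")
  mark(is.na(df$beta) | !is.finite(df$beta), "bad_beta")
  out <- summary_stats(df[keep, , drop = FALSE], trait_id, trait_type,
                       check = FALSE)
  attr(out, "drop_report") <- drop
  if (!quiet && sum(drop) > 0) {
    message(sum(drop), " row(s) dropped while reading ", path, " (",
            paste(names(drop)[drop > 0], drop[drop > 0], sep = "=",
                  collapse = ", "), ")")
  }
  out
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Writes the canonical header (`SNP CHR POS EA OA BETA SE P EAF N`).
#' Numeric fields are serialized with 17 significant digits so that
#' reading the file back reproduces every value bit-for-bit.
#'
#' @param table a `summary_stats` object.
#' @param path destination file.
#' @return Invisibly, the path.
#' @export
write_summary_stats <- function(table, path) {
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    SNP = table$snp, CHR = ifelse(is.na(table$chrom), "NA", table$chrom),
    POS = ifelse(is.na(table$pos), "NA", as.character(table$pos)),
    EA = table$effect_allele, OA = table$other_allele,
    BETA = num(table$beta), SE = num(table$se), P = num(table$pval),
    EAF = num(table$eaf),
    N = ifelse(is.na(table$n), "NA", as.character(table$n)),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a column-map configuration file
#'
#' Plain `key: value` text, one mapping per line; keys are canonical
#' column names (`SNP`, `BETA`, ...), values the file's column names.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path configuration file.
#' @return Named character vector usable as `column_map` in
#'   [read_summary_stats()].
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed column-map line: ", lines[bad][1])
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- trimws(vapply(parts, `[[`, "", 2L))
  stats::setNames(vals, keys)
}
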