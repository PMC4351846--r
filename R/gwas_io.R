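#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited association file with a header row.
#' Canonical column names are `SNP`, `CHR`, `POS`, `P`; `column_map` renames
#' them for files using a different dialect (values are the column names as
#' they appear in the file). Rows with an unparsable position, a missing SNP
#' id, or a P-value outside (0, 1] are dropped; the dropped count is reported
#' in a warning and recorded in the `"n_dropped"` attribute. P = 0 rows are
#' rejected rather than clamped because -log10(0) is undefined.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping canonical names
#'   (`SNP`, `CHR`, `POS`, `P`) to the file's column names.
#' @return A `summary_stats` object: a data.frame with columns `snp`,
#'   `chrom`, `pos` (1-based basepairs) and `p`, sorted by (chrom, pos).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("SNP CHR POS P", "rs1 1 100 0.5", "rs2 1 50 0.01"), f)
#' read_summary_stats(f)
#' @export
read_summary_stats <- function(path,
                               column_map = c(SNP = "SNP", CHR = "CHR",
                                              POS = "POS", P = "P")) {
  if (!file.exists(path)) {
    stop(sprintf("summary file not found: %s", path), call. = FALSE)
  }
  canonical <- c("SNP", "CHR", "POS", "P")
  map <- c(SNP = "SNP", CHR = "CHR", POS = "POS", P = "P")
  map[names(column_map)] <- column_map
  if (!all(canonical %in% names(map))) {
    stop("column_map must cover SNP, CHR, POS, P", call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) {
      stop(sprintf("summary format error in %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  if (nrow(raw) == 0L) {
    stop(sprintf("summary format error: %s has a header but no data rows",
                 path), call. = FALSE)
  }
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop(sprintf("summary format error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(
    snp   = as.character(raw[[map[["SNP"]]]]),
    chrom = as.character(raw[[map[["CHR"]]]]),
    pos   = suppressWarnings(as.numeric(raw[[map[["POS"]]]])),
    p     = suppressWarnings(as.numeric(raw[[map[["P"]]]])),
    stringsAsFactors = FALSE
  )
  keep <- !is.na(df$pos) & df$pos >= 1 & df$pos == floor(df$pos) &
    !is.na(df$p) & df$p > 0 & df$p <= 1 &
    !is.na(df$snp) & nzchar(df$snp)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("summary format error: no valid rows after filtering", call. = FALSE)
  }
  dup <- duplicated(df[, c("chrom", "pos", "snp")])
  if (any(dup)) {
    n_dropped <- n_dropped + sum(dup)
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos, df$snp), , drop = FALSE]
  rownames(df) <- NULL
  if (n_dropped > 0L) {
    warning(sprintf("read_summary_stats: dropped %d invalid/duplicate row(s)",
                    n_dropped), call. = FALSE)
  }
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Write summary statistics in the canonical dialect
#'
#' Tab-delimited with header `SNP CHR POS P`; the inverse of
#' [read_summary_stats()] on its canonical dialect.
#'
#' @param stats A `summary_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(SNP = stats$snp, CHR = stats$chrom,
                    POS = format(stats$pos, scientific = FALSE, trim = TRUE),
                    P = format(stats$p, digits = 17, scientific = TRUE,
                               trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the index SNP of a region
#'
#' By default the SNP with the strongest association (smallest P-value) is
#' chosen; ties are broken by smallest position, then lexicographically by id
#' so the choice is deterministic. The user may instead name any SNP present
#' in the data.
#'
#' @param stats A `summary_stats` object.
#' @param user_snp Optional SNP id overriding the automatic choice.
#' @return A one-row `summary_stats` data.frame (the index record).
#' @export
select_index_snp <- function(stats, user_snp = NULL) {
  if (nrow(stats) == 0L) {
    stop("select_index_snp: empty summary statistics", call. = FALSE)
  }
  if (!is.null(user_snp)) {
    hit <- which(stats$snp == user_snp)
    if (length(hit) == 0L) {
      near <- stats$snp[order(utils::adist(user_snp, stats$snp))]
      stop(sprintf("SNP '%s' not found in summary statistics; nearest ids: %s",
                   user_snp,
                   paste(utils::head(near, 5L), collapse = ", ")),
           call. = FALSE)
    }
    idx <- hit[1L]
  } else {
    ord <- order(stats$p, stats$pos, stats$snp)
    idx <- ord[1L]
  }
  rec <- stats[idx, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Define the plotting window around the index SNP
#'
#' A symmetric window of `flank_bp` basepairs on each side of the index
#' position, clamped at the chromosome origin, expressed 0-based half-open.
#' The window always contains the index position.
#'
#' @param index A one-row index record (from [select_index_snp()]).
#' @param flank_bp Flank size in basepairs on each side (`> 0`).
#' @return A [genomic_interval()].
#' @examples
#' stats <- data.frame(snp = "rs1", chrom = "1", pos = 1000000, p = 1e-8)
#' define_window(stats, 500000)
#' @export
define_window <- function(index, flank_bp) {
  if (!is.numeric(flank_bp) || length(flank_bp) != 1L || is.na(flank_bp) ||
      flank_bp <= 0) {
    stop("define_window: flank_bp must be a positive number", call. = FALSE)
  }
  pos0 <- index$pos - 1
  genomic_interval(index$chrom,
                   max(0, pos0 - flank_bp),
                   pos0 + flank_bp + 1)
}

#' -log10 transform of P-values
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @return `-log10(p)`, elementwise.
#' @export
neglog10 <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("neglog10: p must lie in (0, 1]", call. = FALSE)
  }
  -log10(p)
}

#' Restrict summary statistics to a window
#'
#' @param stats A `summary_stats` object.
#' @param region A [genomic_interval()].
#' @return The rows whose (1-based) position falls inside `region`.
#' @export
stats_in_region <- function(stats, region) {
  keep <- interval_contains_pos(region, stats$pos, stats$chrom)
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}
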