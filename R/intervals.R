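#' Genomic interval (0-based, half-open)
#'
#' The single coordinate convention used throughout the package. All 1-based
#' input formats (summary-statistic positions, VCF, GFF3, WIG) are converted
#' to 0-based half-open at parse time so that interval arithmetic never mixes
#' conventions.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start Integer start, 0-based, `>= 0`.
#' @param end Integer end, exclusive, `> start`.
#' @return An object of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`.
#' @examples
#' gi <- genomic_interval("chr1", 499999, 1500000)
#' interval_length(gi)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end)) {
    stop("genomic_interval: non-numeric coordinates", call. = FALSE)
  }
  if (start < 0) stop("genomic_interval: start must be >= 0", call. = FALSE)
  if (end <= start) {
    stop(sprintf("genomic_interval: end (%s) must be > start (%s)",
                 format(end, scientific = FALSE),
                 format(start, scientific = FALSE)), call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:[%s, %s)  length %s bp\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(interval_length(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Length of a genomic interval in basepairs
#' @param x A `genomic_interval`.
#' @return `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' Half-open overlap test between two intervals
#'
#' Touching intervals (`end == start`) do not overlap.
#'
#' @param a,b `genomic_interval` objects.
#' @return Logical scalar.
#' @export
interval_overlaps <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start < b$end && b$start < a$end
}

#' Does an interval contain a 1-based position?
#' @param x A `genomic_interval`.
#' @param pos 1-based basepair position(s).
#' @param chrom Optional chromosome of `pos`; checked when given.
#' @return Logical vector.
#' @export
interval_contains_pos <- function(x, pos, chrom = NULL) {
  ok <- x$start <= (pos - 1) & (pos - 1) < x$end
  if (!is.null(chrom)) ok <- ok & chrom == x$chrom
  ok
}

#' Clip an interval to lie within another
#' @param x Interval to clip.
#' @param bounds Interval to clip against (same chromosome).
#' @return Clipped `genomic_interval`; errors if the intersection is empty.
#' @export
clip_interval <- function(x, bounds) {
  if (!identical(x$chrom, bounds$chrom)) {
    stop("clip_interval: intervals on different chromosomes", call. = FALSE)
  }
  s <- max(x$start, bounds$start)
  e <- min(x$end, bounds$end)
  if (e <= s) stop("clip_interval: empty intersection", call. = FALSE)
  genomic_interval(x$chrom, s, e)
}

#' Is `inner` fully contained in `outer`?
#' @param inner,outer `genomic_interval` objects.
#' @return Logical scalar.
#' @export
interval_within <- function(inner, outer) {
  identical(inner$chrom, outer$chrom) &&
    inner$start >= outer$start && inner$end <= outer$end
}
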