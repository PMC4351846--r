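#' Horizontal extent of a gene glyph plus its label
#'
#' The label box is `nchar(name) * chars_to_bp` basepairs wide, centered on
#' the transcript midpoint; the extent is the union of the transcript span
#' and the label box, clipped to the plotting region. `chars_to_bp` converts
#' one label character to basepairs at the current panel width (typically
#' region length / panel character capacity).
#'
#' @param gene A `gene_model`.
#' @param region Plotting region ([genomic_interval()]).
#' @param chars_to_bp Basepairs per label character (`> 0`).
#' @return A [genomic_interval()] — the reserved span for this gene.
#' @export
label_extent <- function(gene, region, chars_to_bp) {
  stopifnot(chars_to_bp > 0)
  w <- nchar(gene$name) * chars_to_bp
  mid <- (gene$tx$start + gene$tx$end) / 2
  s <- min(gene$tx$start, mid - w / 2)
  e <- max(gene$tx$end, mid + w / 2)
  genomic_interval(region$chrom, max(region$start, s), min(region$end, e))
}

#' Assign display rows so that nothing overlaps
#'
#' Greedy first-fit over items sorted by extent start (ties broken by end,
#' then name): each item takes the lowest row where it overlaps nothing
#' already placed. For interval inputs processed in start order this greedy
#' coloring is optimal — the number of rows equals the maximum overlap depth
#' of the extent set — so the vertical area occupied by the gene panel is
#' minimal.
#'
#' @param extents Data frame with columns `name`, `start`, `end` (one row
#'   per gene, the [label_extent()] span).
#' @return The same data frame with an integer `row` column (0-based),
#'   rows in the original input order.
#' @examples
#' layout_rows(data.frame(name = c("A", "B", "C"),
#'                        start = c(0, 5, 12), end = c(10, 15, 20)))
#' @export
layout_rows <- function(extents) {
  stopifnot(is.data.frame(extents),
            all(c("name", "start", "end") %in% names(extents)))
  n <- nrow(extents)
  extents$row <- integer(n)
  if (n == 0L) return(extents)
  ord <- order(extents$start, extents$end, extents$name)
  row_end <- numeric(0)          # rightmost occupied coordinate per row
  rows <- integer(n)
  for (i in ord) {
    fit <- which(row_end <= extents$start[i])
    if (length(fit) == 0L) {
      row_end <- c(row_end, extents$end[i])
      rows[i] <- length(row_end) - 1L
    } else {
      r <- fit[1L]
      row_end[r] <- extents$end[i]
      rows[i] <- r - 1L
    }
  }
  extents$row <- rows
  extents
}

#' Compute gene-panel layout for a region
#'
#' Convenience wrapper: derives each gene's [label_extent()] and runs
#' [layout_rows()].
#'
#' @param genes List of `gene_model` objects.
#' @param region Plotting region.
#' @param panel_chars Nominal character capacity of the panel width; the
#'   label-width scale is `interval_length(region) / panel_chars`.
#' @return Data frame `name`, `start`, `end`, `row` (one row per gene, input
#'   order preserved).
#' @export
layout_genes <- function(genes, region, panel_chars = 120) {
  chars_to_bp <- interval_length(region) / panel_chars
  ext <- lapply(genes, label_extent, region = region,
                chars_to_bp = chars_to_bp)
  df <- data.frame(
    name = vapply(genes, function(g) g$name, character(1)),
    start = vapply(ext, function(e) e$start, numeric(1)),
    end = vapply(ext, function(e) e$end, numeric(1)),
    stringsAsFactors = FALSE
  )
  layout_rows(df)
}
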