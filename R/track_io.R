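#' Construct an annotation track
#'
#' A track is either a set of interval features (`kind = "intervals"` or
#' `"ld"`) or a continuous signal (`kind = "signal"`). Interval features
#' carry optional name, value, strand and color (hex string); chromatin-state
#' style tracks are plain interval tracks whose name/color encode the state.
#'
#' @param label Display label.
#' @param kind One of `"intervals"`, `"signal"`, `"ld"`.
#' @param features Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `value`, `strand`, `color`
#'   (for `kind` `"intervals"`/`"ld"`).
#' @param signal Data frame with columns `chrom`, `start`, `end`, `value`
#'   (for `kind = "signal"`; `start` is the 0-based anchor position and must
#'   be strictly increasing).
#' @param display Named list of display defaults (e.g. `color`, `height`).
#' @return A `track` object.
#' @export
new_track <- function(label, kind, features = NULL, signal = NULL,
                      display = list()) {
  kind <- match.arg(kind, c("intervals", "signal", "ld"))
  if (kind == "signal") {
    stopifnot(is.data.frame(signal),
              all(c("chrom", "start", "end", "value") %in% names(signal)))
    if (nrow(signal) > 1L && any(diff(signal$start) <= 0)) {
      stop(sprintf("track '%s': signal positions must be strictly increasing",
                   label), call. = FALSE)
    }
    features <- NULL
  } else {
    if (is.null(features)) {
      features <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0))
    }
    stopifnot(is.data.frame(features),
              all(c("chrom", "start", "end") %in% names(features)))
    for (col in c("name", "strand", "color")) {
      if (is.null(features[[col]])) {
        features[[col]] <- rep(NA_character_, nrow(features))
      }
    }
    if (is.null(features$value)) {
      features$value <- rep(NA_real_, nrow(features))
    }
    if (any(features$end <= features$start)) {
      stop(sprintf("track '%s': interval with end <= start", label),
           call. = FALSE)
    }
    signal <- NULL
  }
  structure(list(label = label, kind = kind, features = features,
                 signal = signal, display = display),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  n <- if (x$kind == "signal") nrow(x$signal) else nrow(x$features)
  cat(sprintf("<track> '%s' (%s), %d %s\n", x$label, x$kind, n,
              if (x$kind == "signal") "signal points" else "features"))
  invisible(x)
}

# rtracklayer::import with errors re-thrown as format errors naming the file
import_or_format_error <- function(path, format) {
  if (!file.exists(path)) {
    stop(sprintf("track file not found: %s", path), call. = FALSE)
  }
  tryCatch(rtracklayer::import(path, format = format),
           error = function(e) {
             stop(sprintf("%s format error in %s: %s", toupper(format), path,
                          conditionMessage(e)), call. = FALSE)
           })
}

grange_color <- function(gr) {
  col <- S4Vectors::mcols(gr)$itemRgb
  if (is.null(col)) rep(NA_character_, length(gr)) else as.character(col)
}

#' Parse a BED file into an interval track
#'
#' BED3–BED9 is accepted; `track`/`browser` header lines are skipped. BED is
#' already 0-based half-open so coordinates are taken verbatim. Field 4 maps
#' to the feature name, field 5 (score) to its value, and field 9 (itemRgb)
#' to its color.
#'
#' @param path Path to the BED file.
#' @param label Track label (defaults to the file base name).
#' @return A `track` of kind `"intervals"`.
#' @export
parse_bed <- function(path, label = basename(path)) {
  gr <- import_or_format_error(path, "bed")
  if (length(gr) > 0L && any(GenomicRanges::width(gr) < 1L)) {
    bad <- which(GenomicRanges::width(gr) < 1L)[1L]
    stop(sprintf("BED format error in %s: end <= start at record %d",
                 path, bad), call. = FALSE)
  }
  mc <- S4Vectors::mcols(gr)
  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (!is.null(mc$name)) as.character(mc$name) else NA_character_,
    value = if (!is.null(mc$score)) as.numeric(mc$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    color = grange_color(gr),
    stringsAsFactors = FALSE
  )
  feat$strand[feat$strand == "*"] <- "."
  new_track(label, "intervals", features = feat)
}

#' Parse a wiggle (WIG) file into a signal track
#'
#' Handles `fixedStep` and `variableStep` declarations; 1-based WIG starts
#' are converted to 0-based. Consecutive declaration blocks are concatenated
#' and strictly increasing positions enforced (out-of-order blocks are sorted
#' with a warning; duplicate positions are a format error).
#'
#' @inheritParams parse_bed
#' @return A `track` of kind `"signal"`; each point spans its WIG span.
#' @export
parse_wiggle <- function(path, label = basename(path)) {
  decls <- grep("^fixedStep", readLines(path), value = TRUE)
  steps <- suppressWarnings(
    as.numeric(sub(".*step=([-0-9.]+).*", "\\1", decls)))
  if (any(!is.na(steps) & steps <= 0)) {
    stop(sprintf("WIG format error in %s: non-positive step", path),
         call. = FALSE)
  }
  gr <- import_or_format_error(path, "wig")
  sig <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    value = as.numeric(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sig[, c("chrom", "start")])) {
    stop(sprintf("WIG format error in %s: duplicate positions", path),
         call. = FALSE)
  }
  if (nrow(sig) > 1L && is.unsorted(sig$start, strictly = TRUE)) {
    warning(sprintf("parse_wiggle: %s positions out of order; sorting", path),
            call. = FALSE)
    sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
    rownames(sig) <- NULL
  }
  new_track(label, "signal", signal = sig)
}

#' Parse a bedGraph file into a signal track
#'
#' Four columns chrom/start/end/value, 0-based half-open kept verbatim. Each
#' record becomes one step anchored at its start, with the interval retained
#' for rendering. Overlapping records are a format error (the format forbids
#' them); out-of-order records are sorted with a warning.
#'
#' @inheritParams parse_bed
#' @return A `track` of kind `"signal"`.
#' @export
parse_bedgraph <- function(path, label = basename(path)) {
  gr <- import_or_format_error(path, "bedGraph")
  if (length(gr) > 1L) {
    hits <- GenomicRanges::countOverlaps(gr, gr)
    if (any(hits > 1L)) {
      stop(sprintf("bedGraph format error in %s: overlapping intervals at record %d",
                   path, which(hits > 1L)[1L]), call. = FALSE)
    }
  }
  sig <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    value = as.numeric(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE
  )
  if (nrow(sig) > 1L && is.unsorted(sig$start, strictly = TRUE)) {
    warning(sprintf("parse_bedgraph: %s records out of order; sorting", path),
            call. = FALSE)
    sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
    rownames(sig) <- NULL
  }
  new_track(label, "signal", signal = sig)
}

#' Construct a gene model
#'
#' @param name Gene/transcript symbol.
#' @param strand `"+"` or `"-"`.
#' @param tx Transcript span as a [genomic_interval()].
#' @param exons Data frame with `start`, `end` (0-based half-open), sorted
#'   and non-overlapping, all within `tx`.
#' @return A `gene_model` object.
#' @export
gene_model <- function(name, strand, tx, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) {
    stop(sprintf("gene_model '%s': exon with end <= start", name),
         call. = FALSE)
  }
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop(sprintf("gene_model '%s': overlapping exons", name), call. = FALSE)
  }
  if (min(exons$start) < tx$start || max(exons$end) > tx$end) {
    stop(sprintf("gene_model '%s': exons extend beyond transcript", name),
         call. = FALSE)
  }
  structure(list(name = name, strand = strand, tx = tx, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:[%s, %s), %d exon(s)\n", x$name,
              x$strand, x$tx$chrom, x$tx$start, x$tx$end, nrow(x$exons)))
  invisible(x)
}

#' Parse gene models from BED12 or GFF3
#'
#' BED12 blocks become exons directly (BED is 0-based half-open). GFF3
#' (1-based closed) is converted at parse time: exons are grouped under their
#' `Parent` mRNA/transcript; a gene with direct exon children and no
#' transcript yields one model. Strand is required. Within-transcript
#' overlapping exons are merged.
#'
#' @param path Path to the gene-model file.
#' @param format `"bed12"` or `"gff3"`.
#' @return A list of `gene_model` objects.
#' @export
parse_gene_models <- function(path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "bed12") {
    raw <- readLines(path)
    data_lines <- raw[!grepl("^(track|browser|#)", raw) & nzchar(raw)]
    for (li in seq_along(data_lines)) {
      f <- strsplit(data_lines[li], "\t", fixed = TRUE)[[1]]
      if (length(f) >= 12L) {
        n_blocks <- suppressWarnings(as.integer(f[10]))
        n_sizes <- length(strsplit(sub(",$", "", f[11]), ",")[[1]])
        n_starts <- length(strsplit(sub(",$", "", f[12]), ",")[[1]])
        if (is.na(n_blocks) || n_sizes != n_blocks || n_starts != n_blocks) {
          stop(sprintf(
            "BED12 format error in %s: blockSizes/blockStarts arity mismatch at line %d",
            path, li), call. = FALSE)
        }
      }
    }
    gr <- import_or_format_error(path, "bed")
    if (is.null(S4Vectors::mcols(gr)$blocks)) {
      stop(sprintf("BED12 format error in %s: missing block fields", path),
           call. = FALSE)
    }
    exlist <- rtracklayer::blocks(gr)   # absolute 1-based exon coordinates
    models <- vector("list", length(gr))
    for (i in seq_along(gr)) {
      strand <- as.character(GenomicRanges::strand(gr[i]))
      if (!strand %in% c("+", "-")) {
        stop(sprintf("BED12 format error in %s: record %d lacks a strand",
                     path, i), call. = FALSE)
      }
      ex <- IRanges::reduce(exlist[[i]])
      models[[i]] <- gene_model(
        name = as.character(S4Vectors::mcols(gr)$name[i]),
        strand = strand,
        tx = genomic_interval(as.character(GenomicRanges::seqnames(gr[i])),
                              GenomicRanges::start(gr[i]) - 1,
                              GenomicRanges::end(gr[i])),
        exons = data.frame(start = GenomicRanges::start(ex) - 1,
                           end = GenomicRanges::end(ex)))
    }
    return(models)
  }

  gr <- import_or_format_error(path, "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_exon)) {
    stop(sprintf("GFF3 format error in %s: no exon features", path),
         call. = FALSE)
  }
  parent <- vapply(mc$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  if (any(is_exon & is.na(parent))) {
    stop(sprintf("GFF3 format error in %s: exon without Parent attribute",
                 path), call. = FALSE)
  }
  parents <- ifelse(is_tx | type == "gene", as.character(mc$ID),
                    NA_character_)
  container_idx <- which(!is.na(parents) & parents %in% parent[is_exon])
  models <- list()
  for (i in container_idx) {
    pid <- parents[i]
    ex_idx <- which(is_exon & parent == pid)
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-")) {
      stop(sprintf("GFF3 format error in %s: feature '%s' lacks a strand",
                   path, pid), call. = FALSE)
    }
    nm <- if (!is.null(mc$Name) && !is.na(mc$Name[i])) {
      as.character(mc$Name[i])
    } else pid
    ex <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(gr[ex_idx]),
                                           GenomicRanges::end(gr[ex_idx])))
    models[[length(models) + 1L]] <- gene_model(
      name = nm, strand = strand,
      tx = genomic_interval(as.character(GenomicRanges::seqnames(gr[i])),
                            GenomicRanges::start(gr[i]) - 1,
                            GenomicRanges::end(gr[i])),
      exons = data.frame(start = IRanges::start(ex) - 1,
                         end = IRanges::end(ex)))
  }
  if (length(models) == 0L) {
    stop(sprintf("GFF3 format error in %s: no gene/mRNA with exon children",
                 path), call. = FALSE)
  }
  models
}

#' Parse a recombination (genetic) map
#'
#' HapMap-style delimited text with a header; only the first two columns
#' (physical position in bp, rate in cM/Mb) are used. Unsorted rows are
#' sorted with a warning; duplicate positions collapse to the last value.
#'
#' @param path Path to the genetic-map file.
#' @return A `genetic_map`: data.frame with columns `pos` (1-based bp,
#'   strictly increasing) and `rate` (cM/Mb, `>= 0`).
#' @export
parse_genetic_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("genetic map not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("genetic map format error in %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  if (ncol(raw) < 2L || nrow(raw) == 0L) {
    stop(sprintf("genetic map format error in %s: need position and rate columns",
                 path), call. = FALSE)
  }
  map <- data.frame(pos = suppressWarnings(as.numeric(raw[[1]])),
                    rate = suppressWarnings(as.numeric(raw[[2]])))
  if (any(is.na(map$pos)) || any(is.na(map$rate))) {
    stop(sprintf("genetic map format error in %s: non-numeric position or rate",
                 path), call. = FALSE)
  }
  if (any(map$rate < 0)) {
    stop(sprintf("genetic map format error in %s: negative recombination rate",
                 path), call. = FALSE)
  }
  if (is.unsorted(map$pos)) {
    warning(sprintf("parse_genetic_map: %s positions out of order; sorting",
                    path), call. = FALSE)
    map <- map[order(map$pos), , drop = FALSE]
  }
  dup <- duplicated(map$pos, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("parse_genetic_map: %d duplicate position(s) collapsed to the last value",
                    sum(dup)), call. = FALSE)
    map <- map[!dup, , drop = FALSE]
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Recombination rate at arbitrary positions
#'
#' Linear interpolation between flanking map points; constant extrapolation
#' of the nearest endpoint outside the map range (no artificial rate cliff at
#' window edges).
#'
#' @param map A `genetic_map`.
#' @param pos Numeric vector of basepair positions.
#' @return Rates in cM/Mb, same length as `pos`.
#' @export
recomb_rate_at <- function(map, pos) {
  if (!is.data.frame(map) || nrow(map) == 0L) {
    stop("recomb_rate_at: empty genetic map", call. = FALSE)
  }
  if (nrow(map) == 1L) return(rep(map$rate[1L], length(pos)))
  stats::approx(map$pos, map$rate, xout = pos, rule = 2)$y
}

#' Window a track to a region
#'
#' Interval features are kept when they overlap the region (half-open test:
#' touching does not overlap); signal points are kept when their anchor
#' position lies inside the region. Order is preserved.
#'
#' @param track A `track`.
#' @param region A [genomic_interval()].
#' @return A `track` of the same kind containing only in-region content.
#' @export
features_in <- function(track, region) {
  if (track$kind == "signal") {
    s <- track$signal
    keep <- s$chrom == region$chrom & s$start >= region$start &
      s$start < region$end
    out <- s[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(new_track(track$label, "signal", signal = out,
                     display = track$display))
  }
  f <- track$features
  keep <- f$chrom == region$chrom & f$start < region$end &
    f$end > region$start
  out <- f[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_track(track$label, track$kind, features = out, display = track$display)
}
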