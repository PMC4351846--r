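#' Build the per-locus annotation report
#'
#' Collects, for one locus: the index SNP, the region, every gene whose
#' transcript overlaps the region, the LD of each panel variant with the
#' index, the track features overlapping the region, and the track features
#' overlapping the index position itself. This is the machine-readable
#' annotation object that accompanies (or replaces) the figure.
#'
#' @param region Locus window ([genomic_interval()]).
#' @param stats `summary_stats` for the locus.
#' @param ld Optional `ld_result` (`NULL` allowed).
#' @param genes List of `gene_model`s.
#' @param tracks List of `track`s (interval tracks contribute hits; signal
#'   tracks contribute in-region points).
#' @param index Optional index record; defaults to [select_index_snp()] on
#'   the windowed stats (or the LD index when present).
#' @return A `locus_report` object.
#' @export
build_report <- function(region, stats, ld = NULL, genes = list(),
                         tracks = list(), index = NULL) {
  stats_w <- stats_in_region(stats, region)
  if (is.null(index)) {
    index <- if (!is.null(ld) && ld$index_id %in% stats_w$snp) {
      stats_w[stats_w$snp == ld$index_id, , drop = FALSE]
    } else {
      select_index_snp(stats_w)
    }
  }
  gsel <- Filter(function(g) interval_overlaps(g$tx, region), genes)
  gene_df <- data.frame(
    name = vapply(gsel, function(g) g$name, character(1)),
    chrom = vapply(gsel, function(g) g$tx$chrom, character(1)),
    start = vapply(gsel, function(g) g$tx$start, numeric(1)),
    end = vapply(gsel, function(g) g$tx$end, numeric(1)),
    strand = vapply(gsel, function(g) g$strand, character(1)),
    stringsAsFactors = FALSE)

  labels <- vapply(tracks, function(t) t$label, character(1))
  track_hits <- lapply(tracks, function(t) {
    w <- features_in(t, region)
    if (w$kind == "signal") w$signal else w$features
  })
  names(track_hits) <- labels
  ipos <- index$pos
  index_hits <- lapply(tracks, function(t) {
    if (t$kind == "signal") {
      hit <- t$signal[t$signal$chrom == index$chrom &
                        t$signal$start <= (ipos - 1) &
                        t$signal$end > (ipos - 1), , drop = FALSE]
    } else {
      hit <- t$features[t$features$chrom == index$chrom &
                          t$features$start <= (ipos - 1) &
                          t$features$end > (ipos - 1), , drop = FALSE]
    }
    rownames(hit) <- NULL
    hit
  })
  names(index_hits) <- labels

  structure(list(
    index = list(snp = index$snp, chrom = index$chrom, pos = index$pos,
                 p = index$p),
    region = list(chrom = region$chrom, start = region$start,
                  end = region$end),
    genes = gene_df,
    ld = list(index_id = if (is.null(ld)) NA_character_ else ld$index_id,
              population = if (is.null(ld)) NA_character_ else ld$population,
              r2 = if (is.null(ld)) stats::setNames(numeric(0), character(0))
                   else ld$r2),
    track_hits = track_hits,
    index_hits = index_hits),
    class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("<locus_report> index %s @ %s:%s, %d gene(s), %d track(s)\n",
              x$index$snp, x$index$chrom,
              format(x$index$pos, big.mark = ","), nrow(x$genes),
              length(x$track_hits)))
  invisible(x)
}

report_df_defaults <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Serialize a locus report
#'
#' JSON: one document with stable key order and explicit empty arrays (a
#' report with no genes has `"genes": []`, never an absent key); reading it
#' back with [read_report()] reconstructs an equal report. TSV: one
#' long-format row per (section, item) with a header line.
#'
#' @param report A `locus_report`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      index = report$index,
      region = report$region,
      genes = report_df_defaults(report$genes),
      ld = list(index_id = report$ld$index_id,
                population = report$ld$population,
                r2 = as.list(report$ld$r2)),
      track_hits = lapply(report$track_hits, report_df_defaults),
      index_hits = lapply(report$index_hits, report_df_defaults)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", dataframe = "rows",
                         pretty = TRUE)
    return(invisible(path))
  }
  rows <- list()
  add <- function(section, track, name, chrom, start, end, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, track = track, name = name, chrom = chrom,
      start = start, end = end, value = value, stringsAsFactors = FALSE)
  }
  if (nrow(report$genes) > 0L) {
    for (i in seq_len(nrow(report$genes))) {
      g <- report$genes[i, ]
      add("gene", NA, g$name, g$chrom, g$start, g$end, NA)
    }
  }
  emit_hits <- function(section, hits) {
    for (lab in names(hits)) {
      h <- hits[[lab]]
      if (nrow(h) == 0L) next
      for (i in seq_len(nrow(h))) {
        add(section, lab,
            if (!is.null(h$name)) h$name[i] else NA,
            h$chrom[i], h$start[i], h$end[i],
            if (!is.null(h$value)) h$value[i] else NA)
      }
    }
  }
  emit_hits("track_hit", report$track_hits)
  emit_hits("index_hit", report$index_hits)
  out <- if (length(rows) == 0L) {
    data.frame(section = character(0), track = character(0),
               name = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), value = numeric(0))
  } else {
    do.call(rbind, rows)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read back a JSON locus report
#'
#' Inverse of [write_report()] with `format = "json"`.
#'
#' @param path Path to the JSON report.
#' @return A `locus_report` equal (up to numeric representation) to the one
#'   written.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  as_df <- function(x, template) {
    if (is.data.frame(x) && nrow(x) > 0L) return(x)
    as.data.frame(template, stringsAsFactors = FALSE)
  }
  gene_cols <- list(name = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    strand = character(0))
  hit_cols <- list(chrom = character(0), start = numeric(0),
                   end = numeric(0), name = character(0),
                   value = numeric(0), strand = character(0),
                   color = character(0))
  genes <- as_df(doc$genes, gene_cols)
  r2 <- vapply(doc$ld$r2, function(v) if (is.null(v)) NA_real_ else
    as.numeric(v), numeric(1))
  fix_hits <- function(hits) {
    if (is.null(hits) || length(hits) == 0L) {
      return(stats::setNames(list(), character(0)))
    }
    lapply(hits, as_df, template = hit_cols)
  }
  structure(list(
    index = doc$index, region = doc$region, genes = genes,
    ld = list(index_id = doc$ld$index_id, population = doc$ld$population,
              r2 = r2),
    track_hits = fix_hits(doc$track_hits),
    index_hits = fix_hits(doc$index_hits)),
    class = "locus_report")
}
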