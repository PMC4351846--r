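#' Default color palette for LD bins and the index SNP
#'
#' The conventional regional-plot ramp: blue (lowest r2) through sky blue,
#' green and orange to red (highest), grey for missing r2, purple for the
#' index SNP. Any named subset can be overridden in [figure_spec()].
#'
#' @return Named character vector of hex colors over [ld_bin_levels()] plus
#'   `"index"`.
#' @export
ld_palette <- function() {
  c("0.0-0.2" = "#2B3990", "0.2-0.4" = "#87CEEB", "0.4-0.6" = "#33A02C",
    "0.6-0.8" = "#FFA500", "0.8-1.0" = "#E31A1C", "missing" = "#BEBEBE",
    "index" = "#7D26CD")
}

#' Specification of a multi-panel locus figure
#'
#' Panels are drawn top to bottom: (a) association scatter with optional
#' recombination overlay, (b) gene models, (c) annotation tracks, and an
#' optional zoom panel. Between 1 and 10 tracks are accepted.
#'
#' @param region Plot window ([genomic_interval()]).
#' @param tracks List of 1–10 [new_track()] objects.
#' @param yaxis_mode `"pvalue"` (-log10 P on the left axis) or `"ld"`
#'   (r2 on the left axis; requires an LD result at render time).
#' @param show_recomb Draw the recombination-rate curve on the right axis
#'   (needs a genetic map at render time).
#' @param zoom Optional zoom definition: `list(mode = "factor", factor = k)`
#'   with `k > 1`, or `list(mode = "ld_cutoff", cutoff = c)` with c in
#'   (0, 1].
#' @param snp_track Append a tick track showing every assessed SNP in the
#'   association panel's LD colors.
#' @param palette Named color overrides for [ld_palette()] entries.
#' @param panel_chars Character capacity used for gene-label widths
#'   (see [layout_genes()]).
#' @return A `figure_spec` object.
#' @export
figure_spec <- function(region, tracks, yaxis_mode = c("pvalue", "ld"),
                        show_recomb = TRUE, zoom = NULL, snp_track = TRUE,
                        palette = NULL, panel_chars = 120) {
  yaxis_mode <- match.arg(yaxis_mode)
  if (!is.list(tracks) || length(tracks) < 1L || length(tracks) > 10L) {
    stop(sprintf("figure_spec: between 1 and 10 tracks required, got %d",
                 length(tracks)), call. = FALSE)
  }
  if (!all(vapply(tracks, inherits, logical(1), "track"))) {
    stop("figure_spec: tracks must be 'track' objects", call. = FALSE)
  }
  if (!is.null(zoom)) {
    if (!is.list(zoom) || is.null(zoom$mode) ||
        !zoom$mode %in% c("factor", "ld_cutoff")) {
      stop("figure_spec: zoom$mode must be 'factor' or 'ld_cutoff'",
           call. = FALSE)
    }
    if (zoom$mode == "factor" &&
        (is.null(zoom$factor) || zoom$factor <= 1)) {
      stop("figure_spec: zoom factor must be > 1", call. = FALSE)
    }
    if (zoom$mode == "ld_cutoff" &&
        (is.null(zoom$cutoff) || zoom$cutoff <= 0 || zoom$cutoff > 1)) {
      stop("figure_spec: ld cutoff must lie in (0, 1]", call. = FALSE)
    }
  }
  pal <- ld_palette()
  if (!is.null(palette)) pal[names(palette)] <- palette
  structure(list(region = region, tracks = tracks, yaxis_mode = yaxis_mode,
                 show_recomb = show_recomb, zoom = zoom,
                 snp_track = snp_track, palette = pal,
                 panel_chars = panel_chars),
            class = "figure_spec")
}

#' Zoom sub-region below the main panels
#'
#' Factor mode: an interval centered on the index position of length
#' `region length / k`, clipped to the region; when the index sits near a
#' region edge the window shifts inward to preserve its length rather than
#' shrinking. LD-cutoff mode delegates to [ld_cutoff_region()] and clips.
#' The result always contains the index position.
#'
#' @param spec A [figure_spec()] with `zoom` configured.
#' @param index Index SNP record (one-row `summary_stats`).
#' @param ld `ld_result`, required for `ld_cutoff` mode.
#' @param positions Named id -> 1-based position map, required for
#'   `ld_cutoff` mode.
#' @return A [genomic_interval()] contained in `spec$region`.
#' @export
zoom_region <- function(spec, index, ld = NULL, positions = NULL) {
  if (is.null(spec$zoom)) stop("zoom_region: no zoom configured",
                               call. = FALSE)
  region <- spec$region
  if (spec$zoom$mode == "factor") {
    k <- spec$zoom$factor
    if (k <= 1) stop("zoom_region: factor must be > 1", call. = FALSE)
    len <- min(round(interval_length(region) / k), interval_length(region))
    start <- round(index$pos - len / 2)
    if (start < region$start) start <- region$start
    if (start + len > region$end) start <- region$end - len
    return(genomic_interval(region$chrom, start, start + len))
  }
  if (is.null(ld) || is.null(positions)) {
    stop("zoom_region: ld result and positions required for ld_cutoff mode",
         call. = FALSE)
  }
  r <- ld_cutoff_region(ld, positions, spec$zoom$cutoff, region$chrom)
  clip_interval(r, region)
}

#' SNP tick track with the association panel's LD colors
#'
#' One 1-bp tick per assessed SNP, colored by its LD bin with the index;
#' the index SNP gets the index color. Shares [assign_ld_bin()] and the
#' figure palette with the association panel so the two displays always
#' agree.
#'
#' @param stats `summary_stats` (typically already windowed).
#' @param ld `ld_result`, or `NULL` (all ticks take the missing color).
#' @param palette Color map as in [ld_palette()].
#' @return A `track` of kind `"ld"` with a feature per SNP (extra columns
#'   `bin` and `is_index`).
#' @export
build_snp_track <- function(stats, ld = NULL, palette = ld_palette()) {
  r2 <- if (is.null(ld)) rep(NA_real_, nrow(stats)) else
    unname(ld$r2[stats$snp])
  bin <- assign_ld_bin(r2)
  is_index <- if (is.null(ld)) rep(FALSE, nrow(stats)) else
    stats$snp == ld$index_id
  bin[is_index] <- "index"
  feat <- data.frame(chrom = stats$chrom, start = stats$pos - 1,
                     end = stats$pos, name = stats$snp, value = r2,
                     strand = NA_character_,
                     color = unname(palette[bin]), bin = bin,
                     is_index = is_index, stringsAsFactors = FALSE)
  new_track("SNPs", "ld", features = feat)
}

# association-panel point table (also the manifest "points" section)
panel_points <- function(stats, ld, yaxis_mode, palette) {
  r2 <- if (is.null(ld)) rep(NA_real_, nrow(stats)) else
    unname(ld$r2[stats$snp])
  bin <- assign_ld_bin(r2)
  is_index <- if (is.null(ld)) rep(FALSE, nrow(stats)) else
    stats$snp == ld$index_id
  bin[is_index] <- "index"
  y <- if (yaxis_mode == "pvalue") neglog10(stats$p) else
    ifelse(is.na(r2), 0, r2)
  data.frame(snp = stats$snp, pos = stats$pos, x = stats$pos, y = y,
             r2 = r2, bin = bin, color = unname(palette[bin]),
             is_index = is_index, stringsAsFactors = FALSE)
}

mb <- function(x) x / 1e6

draw_track_lane <- function(track, y0, h, region) {
  if (track$kind == "signal") {
    s <- track$signal
    if (nrow(s) == 0L) return(invisible())
    v <- s$value
    vmax <- max(v, 1e-9)
    graphics::segments(mb(s$start), y0, mb(s$start), y0 + h * 0.9 * v / vmax,
                       col = "#4477AA", lwd = 1)
    graphics::lines(mb(s$start), y0 + h * 0.9 * v / vmax, col = "#4477AA")
  } else {
    f <- track$features
    if (nrow(f) == 0L) return(invisible())
    col <- ifelse(is.na(f$color), "#4477AA", f$color)
    if (track$kind == "ld") {
      graphics::segments(mb(f$start), y0, mb(f$start), y0 + h * 0.9,
                         col = col, lwd = 1.2)
    } else {
      graphics::rect(mb(f$start), y0 + h * 0.15, mb(f$end), y0 + h * 0.85,
                     col = col, border = NA)
    }
  }
  invisible()
}

draw_tracks_panel <- function(tracks, region, xlab = NULL) {
  n <- length(tracks)
  graphics::plot(NA, xlim = mb(c(region$start, region$end)), ylim = c(0, n),
                 xlab = if (is.null(xlab)) "" else xlab, ylab = "",
                 axes = FALSE)
  if (!is.null(xlab)) graphics::axis(1)
  for (i in seq_len(n)) {
    y0 <- n - i               # first track on top
    tr <- features_in(tracks[[i]], region)
    draw_track_lane(tr, y0 + 0.05, 0.9, region)
    graphics::mtext(tracks[[i]]$label, side = 2, at = y0 + 0.5, las = 2,
                    cex = 0.55, line = 0.3)
  }
  invisible()
}

draw_gene_panel <- function(genes, gl, region) {
  nrows <- if (nrow(gl) == 0L) 1L else max(gl$row) + 1L
  graphics::plot(NA, xlim = mb(c(region$start, region$end)),
                 ylim = c(0, nrows), xlab = "", ylab = "", axes = FALSE)
  strand_col <- c("+" = "#1F78B4", "-" = "#E31A1C")
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    y <- nrows - gl$row[i] - 0.5
    col <- strand_col[[g$strand]]
    graphics::segments(mb(g$tx$start), y, mb(g$tx$end), y, col = col,
                       lwd = 1)
    graphics::rect(mb(g$exons$start), y - 0.12, mb(g$exons$end), y + 0.12,
                   col = col, border = col)
    arrow_x <- seq(g$tx$start, g$tx$end, length.out = 6)[2:5]
    code <- if (g$strand == "+") 2 else 1
    suppressWarnings(
      graphics::arrows(mb(arrow_x - 1), y, mb(arrow_x + 1), y, col = col,
                       length = 0.04, code = code))
    graphics::text(mb((g$tx$start + g$tx$end) / 2), y + 0.3, g$name,
                   col = col, cex = 0.6, font = 3)
  }
  invisible()
}

#' Render the multi-panel locus figure
#'
#' Draws, top to bottom: (a) the association scatter (-log10 P or r2 on the
#' left axis, recombination rate in cM/Mb on the right axis, points colored
#' by LD bin, the index SNP highlighted as a purple diamond and labelled),
#' (b) gene models (exon boxes on intron lines; plus strand blue with
#' rightward arrows, minus strand red with leftward arrows; labels placed by
#' [layout_genes()] so nothing overlaps), (c) the annotation tracks in user
#' order (plus the SNP tick track when requested), and the optional zoom
#' panel over a sub-region, drawn without modifying the upper panels.
#'
#' Alongside the image a machine-readable layout manifest (JSON) is written
#' with panel list, point coordinates, gene rows, track lanes and the zoom
#' region, so tests and downstream code can assert geometry without pixel
#' comparison. Rendering is deterministic given identical inputs.
#'
#' @param spec A [figure_spec()].
#' @param stats `summary_stats` for the locus.
#' @param ld Optional `ld_result` (without it points take the missing
#'   color).
#' @param genes List of `gene_model`s.
#' @param map Optional `genetic_map` for the recombination overlay.
#' @param out Output image path.
#' @param format `"png"`, `"pdf"` or `"svg"`.
#' @return Invisibly, a list: `figure` (path), `manifest` (path),
#'   `manifest_data` (the manifest as an R list).
#' @export
render_figure <- function(spec, stats, ld = NULL, genes = list(), map = NULL,
                          out, format = c("png", "pdf", "svg")) {
  format <- match.arg(format)
  if (length(spec$tracks) < 1L || length(spec$tracks) > 10L) {
    stop("render_figure: between 1 and 10 tracks required", call. = FALSE)
  }
  region <- spec$region
  stats_w <- stats_in_region(stats, region)
  if (nrow(stats_w) == 0L) {
    stop("render_figure: no SNPs inside the plotting region", call. = FALSE)
  }
  index <- if (!is.null(ld) && ld$index_id %in% stats_w$snp) {
    stats_w[stats_w$snp == ld$index_id, , drop = FALSE]
  } else {
    select_index_snp(stats_w)
  }
  pts <- panel_points(stats_w, ld, spec$yaxis_mode, spec$palette)
  genes_w <- Filter(function(g) interval_overlaps(g$tx, region), genes)
  gl <- layout_genes(genes_w, region, spec$panel_chars)

  tracks <- spec$tracks
  if (isTRUE(spec$snp_track)) {
    tracks <- c(tracks, list(build_snp_track(stats_w, ld, spec$palette)))
  }
  zoom <- NULL
  if (!is.null(spec$zoom)) {
    zoom <- zoom_region(spec, index, ld,
                        stats::setNames(stats_w$pos, stats_w$snp))
  }

  manifest <- list(
    region = list(chrom = region$chrom, start = region$start,
                  end = region$end),
    panels = c("association", "genes", "tracks", if (!is.null(zoom)) "zoom"),
    yaxis = list(
      mode = spec$yaxis_mode,
      left_label = if (spec$yaxis_mode == "pvalue") "-log10(P)" else "r^2",
      right_label = if (spec$show_recomb && !is.null(map))
        "Recombination rate (cM/Mb)" else NULL),
    index = list(snp = index$snp, pos = index$pos, p = index$p),
    points = pts,
    gene_rows = gl,
    tracks = lapply(seq_along(tracks), function(i) {
      tr <- features_in(tracks[[i]], region)
      list(label = tr$label, kind = tr$kind, lane = i - 1,
           n_features = if (tr$kind == "signal") nrow(tr$signal)
                        else nrow(tr$features))
    }),
    zoom = if (is.null(zoom)) NULL else
      list(chrom = zoom$chrom, start = zoom$start, end = zoom$end,
           mode = spec$zoom$mode)
  )

  n_rows_genes <- if (nrow(gl) == 0L) 1L else max(gl$row) + 1L
  h_assoc <- 3.2
  h_genes <- 0.4 + 0.35 * n_rows_genes
  h_tracks <- 0.35 * length(tracks) + 0.4
  h_zoom <- if (is.null(zoom)) 0 else h_tracks + 0.3
  total_h <- h_assoc + h_genes + h_tracks + h_zoom + 0.6
  width_in <- 9

  switch(format,
         png = grDevices::png(out, width = width_in, height = total_h,
                              units = "in", res = 150),
         pdf = grDevices::pdf(out, width = width_in, height = total_h),
         svg = grDevices::svg(out, width = width_in, height = total_h))
  on.exit(grDevices::dev.off(), add = TRUE)

  heights <- c(h_assoc, h_genes, h_tracks, if (!is.null(zoom)) h_zoom)
  graphics::layout(matrix(seq_along(heights), ncol = 1), heights = heights)
  op <- graphics::par(mar = c(1.2, 4.2, 1.5, 4.2), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op), add = TRUE)

  # (a) association
  ymax <- max(pts$y, if (spec$yaxis_mode == "ld") 1 else 1, na.rm = TRUE)
  graphics::plot(mb(pts$x), pts$y, pch = 20, col = pts$color, cex = 0.8,
                 xlim = mb(c(region$start, region$end)),
                 ylim = c(0, ymax * 1.08),
                 xlab = "", ylab = manifest$yaxis$left_label,
                 main = sprintf("%s:%s-%s", region$chrom,
                                format(region$start, big.mark = ","),
                                format(region$end, big.mark = ",")),
                 cex.main = 0.9)
  if (spec$show_recomb && !is.null(map)) {
    xs <- seq(region$start + 1, region$end, length.out = 500)
    rr <- recomb_rate_at(map, xs)
    graphics::par(new = TRUE)
    graphics::plot(mb(xs), rr, type = "l", col = "#44AA99", lwd = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   xlim = mb(c(region$start, region$end)),
                   ylim = c(0, max(rr) * 1.05 + 1e-9))
    graphics::axis(4, col = "#44AA99", col.axis = "#44AA99", cex.axis = 0.8)
    graphics::mtext("Recombination rate (cM/Mb)", side = 4, line = 2,
                    col = "#44AA99", cex = 0.6)
    graphics::par(new = TRUE)
    graphics::plot(NA, xlim = mb(c(region$start, region$end)),
                   ylim = c(0, ymax * 1.08), axes = FALSE, xlab = "",
                   ylab = "")
  }
  ipt <- pts[pts$is_index | pts$snp == index$snp, , drop = FALSE][1, ]
  graphics::points(mb(ipt$x), ipt$y, pch = 23, cex = 1.3,
                   bg = spec$palette[["index"]])
  graphics::text(mb(ipt$x), ipt$y, labels = ipt$snp, pos = 3, cex = 0.7)
  graphics::legend("topright", legend = names(spec$palette),
                   col = spec$palette, pch = 20, cex = 0.55, bty = "n",
                   title = expression(r^2))

  # (b) genes
  draw_gene_panel(genes_w, gl, region)

  # (c) tracks
  draw_tracks_panel(tracks, region,
                    xlab = if (is.null(zoom))
                      sprintf("Position on %s (Mb)", region$chrom) else NULL)

  # zoom panel
  if (!is.null(zoom)) {
    draw_tracks_panel(lapply(tracks, features_in, region = zoom), zoom,
                      xlab = sprintf("Zoom %s (Mb)", region$chrom))
  }

  manifest_path <- paste0(out, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       dataframe = "rows")
  invisible(list(figure = out, manifest = manifest_path,
                 manifest_data = manifest))
}
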