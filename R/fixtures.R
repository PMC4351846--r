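#' Simulation configuration for synthetic locus data
#'
#' Defines a haplotype-copy LD-block model: each diploid sample carries two
#' haplotypes; within an LD block every SNP copies a block-ancestral allele
#' (frequency 0.5) and flips it independently with probability
#' `within_block_flip_prob`; blocks are independent. This gives controllable,
#' assertable LD structure (near-1 r2 within a block at low flip
#' probability, near-0 across blocks) with trivial code — enough to exercise
#' LD, plotting, and reporting machinery, without claiming coalescent
#' realism.
#'
#' Defaults correspond to the standard synthetic locus used throughout the
#' test suite: 500 samples, 200 SNPs in 1 Mb, blocks of 20 SNPs, 5% flip
#' probability, one causal SNP of effect 1.0 on a unit-variance phenotype.
#'
#' @param n_samples Number of diploid samples.
#' @param n_snps Number of SNPs.
#' @param region Locus span as a [genomic_interval()].
#' @param block_size SNPs per LD block.
#' @param within_block_flip_prob Per-SNP allele flip probability in
#'   `[0, 0.5]`.
#' @param causal_index 1-based index of the causal SNP (in position order);
#'   defaults to the middle SNP.
#' @param effect Additive effect per ALT allele on the phenotype.
#' @param seed Integer seed; all simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 500, n_snps = 200,
                       region = genomic_interval("chr1", 0, 1000000),
                       block_size = 20, within_block_flip_prob = 0.05,
                       causal_index = NULL, effect = 1.0, seed = 42) {
  if (is.null(causal_index)) causal_index <- ceiling((n_snps + 1) / 2)
  stopifnot(n_samples >= 2, n_snps >= 1, block_size >= 1,
            within_block_flip_prob >= 0, within_block_flip_prob <= 0.5,
            causal_index >= 1, causal_index <= n_snps)
  structure(list(n_samples = n_samples, n_snps = n_snps, region = region,
                 block_size = block_size,
                 within_block_flip_prob = within_block_flip_prob,
                 causal_index = causal_index, effect = effect,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate LD-block genotypes
#'
#' See [sim_config()] for the generative model. SNP positions are a sorted
#' uniform draw within the region. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `genotype_matrix` (same structure as [extract_genotypes()]).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  m <- cfg$n_snps
  pos1 <- sort(sample.int(interval_length(cfg$region), m)) + cfg$region$start
  block <- ceiling(seq_len(m) / cfg$block_size)
  n_blocks <- max(block)
  hap <- function() {
    anc <- matrix(stats::rbinom(n * n_blocks, 1, 0.5), nrow = n) # n x blocks
    flips <- matrix(stats::rbinom(n * m, 1, cfg$within_block_flip_prob),
                    nrow = n)
    (anc[, block, drop = FALSE] + flips) %% 2
  }
  dosages <- hap() + hap()
  vid <- sprintf("rs%05d", seq_len(m))
  dimnames(dosages) <- list(sprintf("S%04d", seq_len(n)), vid)
  structure(list(sample_ids = rownames(dosages), variant_ids = vid,
                 pos0 = pos1 - 1, chrom = cfg$region$chrom,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' LD-block index of each simulated SNP
#' @param cfg A [sim_config()].
#' @return Integer vector: block id per SNP (position order).
#' @export
snp_blocks <- function(cfg) ceiling(seq_len(cfg$n_snps) / cfg$block_size)

#' Simulate association P-values from genotypes
#'
#' Phenotype `y = effect * dosage(causal) + N(0, 1)`; each SNP is tested by
#' simple linear regression of `y` on dosage, with the two-sided P-value from
#' the closed-form t statistic on n-2 degrees of freedom. Monomorphic SNPs
#' get P = 1. Deterministic given `cfg$seed` (an offset seed is used so that
#' phenotype noise is independent of the genotype draw).
#'
#' @param genos A `genotype_matrix` from [simulate_genotypes()].
#' @param cfg The [sim_config()] used to generate `genos`.
#' @return A `summary_stats` object (positions from `genos`).
#' @export
simulate_pvalues <- function(genos, cfg) {
  set.seed(cfg$seed + 1L)
  n <- length(genos$sample_ids)
  y <- cfg$effect * genos$dosages[, cfg$causal_index] + stats::rnorm(n)
  r <- suppressWarnings(as.numeric(stats::cor(genos$dosages, y)))
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[is.na(p)] <- 1           # monomorphic variant: no test, no signal
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(snp = genos$variant_ids, chrom = genos$chrom,
                    pos = genos$pos0 + 1, p = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- 0L
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate annotation tracks, gene models, and a genetic map
#'
#' Produces, all within `region` and deterministically given `seed`:
#' an interval track (named, scored features), a continuous signal track,
#' a chromatin-state style track (colored, labelled segments tiling the
#' region), 3–8 gene models with 1–5 exons each, and a piecewise genetic map
#' with one recombination hotspot.
#'
#' @param region A [genomic_interval()].
#' @param seed Integer seed.
#' @return List with elements `tracks` (list of 3 `track`s), `genes`
#'   (list of `gene_model`s), `map` (`genetic_map`).
#' @export
simulate_tracks_and_genes <- function(region, seed = 42) {
  set.seed(seed)
  len <- interval_length(region)
  s0 <- region$start

  n_feat <- 10L
  fs <- sort(sample.int(len - 5000L, n_feat)) + s0
  fw <- sample(500:4000, n_feat, replace = TRUE)
  intervals <- new_track("binding sites", "intervals", features = data.frame(
    chrom = region$chrom, start = fs, end = pmin(fs + fw, region$end),
    name = sprintf("site%02d", seq_len(n_feat)),
    value = round(stats::runif(n_feat, 100, 1000)),
    strand = ".", color = NA_character_, stringsAsFactors = FALSE))

  n_pts <- 200L
  px <- s0 + round(seq(0.002, 0.998, length.out = n_pts) * len)
  pv <- round(pmax(0, 3 + 2 * sin(seq(0, 6 * pi, length.out = n_pts)) +
                     stats::rnorm(n_pts, 0, 0.3)), 4)
  signal <- new_track("conservation", "signal", signal = data.frame(
    chrom = region$chrom, start = px, end = px + 1, value = pv,
    stringsAsFactors = FALSE))

  states <- c(Promoter = "#FF0000", Enhancer = "#FFA500",
              Transcribed = "#008000", Repressed = "#808080",
              Quiescent = "#F0F0F0")
  n_seg <- 12L
  cuts <- sort(sample((s0 + 1):(region$end - 1), n_seg - 1L))
  seg_start <- c(s0, cuts)
  seg_end <- c(cuts, region$end)
  seg_state <- sample(names(states), n_seg, replace = TRUE)
  chromatin <- new_track("chromatin state", "intervals", features = data.frame(
    chrom = region$chrom, start = seg_start, end = seg_end,
    name = seg_state, value = 0, strand = ".",
    color = unname(states[seg_state]), stringsAsFactors = FALSE))

  n_genes <- sample(3:8, 1)
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g_len <- sample(round(len / 50):round(len / 8), 1)
    g_start <- s0 + sample.int(max(1L, len - g_len), 1)
    n_ex <- sample(1:5, 1)
    bounds <- sort(sample(seq(g_start, g_start + g_len), 2 * n_ex))
    exons <- data.frame(start = bounds[seq(1, 2 * n_ex, by = 2)],
                        end = bounds[seq(2, 2 * n_ex, by = 2)])
    exons <- exons[exons$end > exons$start, , drop = FALSE]
    if (nrow(exons) == 0L) {
      exons <- data.frame(start = g_start, end = g_start + g_len)
    }
    exons$start[1] <- g_start
    exons$end[nrow(exons)] <- g_start + g_len
    genes[[i]] <- gene_model(sprintf("GENE%d", i),
                             sample(c("+", "-"), 1),
                             genomic_interval(region$chrom, g_start,
                                              g_start + g_len),
                             exons)
  }

  map_pos <- seq(s0 + 1, region$end, by = max(1, round(len / 100)))
  base <- round(stats::runif(length(map_pos), 0.1, 1.5), 4)
  hotspot <- s0 + round(0.6 * len)
  base <- base + 50 * exp(-((map_pos - hotspot) / (len / 80))^2)
  map <- data.frame(pos = map_pos, rate = round(base, 4))
  class(map) <- c("genetic_map", "data.frame")

  list(tracks = list(intervals, signal, chromatin), genes = genes, map = map)
}

# ---- plain-text writers (controlled dialects; readers go via rtracklayer) --

#' Write an interval track as BED
#'
#' BED9 when any feature carries a color, otherwise BED6. `NA` names become
#' `"."` and `NA` values become score 0.
#'
#' @param track A `track` of kind `"intervals"` or `"ld"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  stopifnot(track$kind %in% c("intervals", "ld"))
  f <- track$features
  nm <- ifelse(is.na(f$name), ".", f$name)
  sc <- ifelse(is.na(f$value), 0, f$value)
  st <- ifelse(is.na(f$strand) | f$strand == "", ".", f$strand)
  if (any(!is.na(f$color))) {
    rgb <- vapply(f$color, function(cl) {
      if (is.na(cl)) "0,0,0" else paste(grDevices::col2rgb(cl), collapse = ",")
    }, character(1))
    lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s", f$chrom,
                     format(f$start, scientific = FALSE, trim = TRUE),
                     format(f$end, scientific = FALSE, trim = TRUE),
                     nm, sc, st,
                     format(f$start, scientific = FALSE, trim = TRUE),
                     format(f$end, scientific = FALSE, trim = TRUE), rgb)
  } else {
    lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", f$chrom,
                     format(f$start, scientific = FALSE, trim = TRUE),
                     format(f$end, scientific = FALSE, trim = TRUE),
                     nm, sc, st)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a signal track as bedGraph
#' @inheritParams write_track_bed
#' @export
write_track_bedgraph <- function(track, path) {
  stopifnot(track$kind == "signal")
  s <- track$signal
  writeLines(sprintf("%s\t%s\t%s\t%s", s$chrom,
                     format(s$start, scientific = FALSE, trim = TRUE),
                     format(s$end, scientific = FALSE, trim = TRUE),
                     format(s$value, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' Write a signal track as variableStep WIG
#'
#' Positions are written 1-based; a new declaration line is emitted whenever
#' the span (end - start) changes.
#'
#' @inheritParams write_track_bed
#' @export
write_track_wig <- function(track, path) {
  stopifnot(track$kind == "signal")
  s <- track$signal
  span <- s$end - s$start
  out <- character(0)
  cur_span <- -1
  for (i in seq_len(nrow(s))) {
    if (span[i] != cur_span) {
      cur_span <- span[i]
      out <- c(out, sprintf("variableStep chrom=%s span=%d", s$chrom[i],
                            as.integer(cur_span)))
    }
    out <- c(out, sprintf("%s %s",
                          format(s$start[i] + 1, scientific = FALSE,
                                 trim = TRUE),
                          format(s$value[i], scientific = FALSE, trim = TRUE)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write gene models as BED12
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    sizes <- g$exons$end - g$exons$start
    starts <- g$exons$start - g$tx$start
    sprintf("%s\t%s\t%s\t%s\t0\t%s\t%s\t%s\t0\t%d\t%s\t%s",
            g$tx$chrom,
            format(g$tx$start, scientific = FALSE, trim = TRUE),
            format(g$tx$end, scientific = FALSE, trim = TRUE),
            g$name, g$strand,
            format(g$tx$start, scientific = FALSE, trim = TRUE),
            format(g$tx$end, scientific = FALSE, trim = TRUE),
            nrow(g$exons),
            paste(format(sizes, scientific = FALSE, trim = TRUE),
                  collapse = ","),
            paste(format(starts, scientific = FALSE, trim = TRUE),
                  collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genetic map (HapMap-style three-column text)
#'
#' The cumulative map (cM) column is derived by trapezoidal integration of
#' the rate; only the first two columns are read back.
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  cm <- c(0, cumsum(diff(map$pos) / 1e6 *
                      (utils::head(map$rate, -1) + utils::tail(map$rate, -1)) / 2))
  out <- data.frame("Position(bp)" = format(map$pos, scientific = FALSE,
                                            trim = TRUE),
                    "Rate(cM/Mb)" = format(map$rate, scientific = FALSE,
                                           trim = TRUE),
                    "Map(cM)" = format(round(cm, 6), scientific = FALSE,
                                       trim = TRUE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF (GT only)
#'
#' All variants are written as A>G SNVs with the stored positions and ids;
#' dosages map to unphased genotypes (0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' `NA` -> ./.).
#'
#' @param genos A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genos, path) {
  gtmap <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", genos$chrom),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genos$sample_ids), collapse = "\t"))
  rows <- vapply(seq_along(genos$variant_ids), function(j) {
    d <- genos$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gtmap[d + 1])
    paste(c(genos$chrom,
            format(genos$pos0[j] + 1, scientific = FALSE, trim = TRUE),
            genos$variant_ids[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a complete synthetic locus to disk in standard formats
#'
#' Generates genotypes, association statistics, tracks, genes and a genetic
#' map from `cfg` and writes them as the files a real run would consume:
#' summary statistics text, VCF, sample list, BED12 gene models, BED /
#' WIG / bedGraph / BED9 tracks, and a genetic-map table. Every parser in
#' the package can therefore be exercised end-to-end against independently
#' written files.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @return Named list of file paths plus the generated objects
#'   (`genos`, `stats`, `sim` = tracks/genes/map).
#' @export
write_fixture_locus <- function(dir, cfg = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genos <- simulate_genotypes(cfg)
  stats <- simulate_pvalues(genos, cfg)
  sim <- simulate_tracks_and_genes(cfg$region, cfg$seed)
  paths <- list(
    summary = file.path(dir, "summary.txt"),
    vcf = file.path(dir, "panel.vcf"),
    samples = file.path(dir, "samples.txt"),
    genes = file.path(dir, "genes.bed12"),
    track_bed = file.path(dir, "binding_sites.bed"),
    track_wig = file.path(dir, "conservation.wig"),
    track_states = file.path(dir, "chromatin_states.bed"),
    map = file.path(dir, "genetic_map.txt")
  )
  write_summary_stats(stats, paths$summary)
  write_vcf(genos, paths$vcf)
  writeLines(genos$sample_ids, paths$samples)
  write_gene_models_bed12(sim$genes, paths$genes)
  write_track_bed(sim$tracks[[1]], paths$track_bed)
  write_track_wig(sim$tracks[[2]], paths$track_wig)
  write_track_bed(sim$tracks[[3]], paths$track_states)
  write_genetic_map(sim$map, paths$map)
  c(paths, list(genos = genos, stats = stats, sim = sim))
}
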