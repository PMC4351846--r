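#' Extract a dosage matrix from a VCF region
#'
#' Reads biallelic SNVs overlapping `region` and converts genotypes to
#' ALT-allele dosages (0/1/2; missing genotypes become `NA`). Multi-allelic
#' sites and indels are skipped and their count reported in a warning.
#' Restricting to a population is done by passing the subset of sample ids.
#'
#' @param vcf Path to a VCF file (plain text or gzipped).
#' @param region A [genomic_interval()].
#' @param samples Optional character vector of sample ids to keep.
#' @return A `genotype_matrix`: list with `sample_ids`, `variant_ids`,
#'   `pos0` (0-based positions), `chrom`, and `dosages`
#'   (samples x variants numeric matrix). Zero variants is a valid,
#'   empty result (warned about) — the caller decides how to degrade.
#' @export
extract_genotypes <- function(vcf, region, samples = NULL) {
  if (!file.exists(vcf)) stop(sprintf("VCF not found: %s", vcf), call. = FALSE)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  id <- as.character(fix[, "ID"])
  id[is.na(id) | id == "."] <- paste0(chrom, ":", pos)[is.na(id) | id == "."]

  in_region <- chrom == region$chrom & (pos - 1) >= region$start &
    (pos - 1) < region$end
  snv <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(in_region & !snv)
  keep <- which(in_region & snv)
  if (n_skipped > 0L) {
    warning(sprintf(
      "extract_genotypes: skipped %d multi-allelic/indel site(s) in region",
      n_skipped), call. = FALSE)
  }

  all_samples <- colnames(v@gt)[-1]
  if (!is.null(samples)) {
    unknown <- setdiff(samples, all_samples)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown sample id(s) in VCF: %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")),
           call. = FALSE)
    }
    use_samples <- samples
  } else {
    use_samples <- all_samples
  }

  if (length(keep) == 0L) {
    warning(sprintf("extract_genotypes: no biallelic SNVs in %s:[%s, %s)",
                    region$chrom, region$start, region$end), call. = FALSE)
    return(structure(list(
      sample_ids = use_samples, variant_ids = character(0),
      pos0 = numeric(0), chrom = region$chrom,
      dosages = matrix(numeric(0), nrow = length(use_samples), ncol = 0,
                       dimnames = list(use_samples, NULL))),
      class = "genotype_matrix"))
  }

  gt <- vcfR::extract.gt(v, element = "GT")   # variants x samples
  gt <- gt[keep, use_samples, drop = FALSE]
  dos <- gt_to_dosage(gt)                     # variants x samples
  dosages <- t(dos)                           # samples x variants
  vid <- make.unique(id[keep])
  dimnames(dosages) <- list(use_samples, vid)
  structure(list(sample_ids = use_samples, variant_ids = vid,
                 pos0 = pos[keep] - 1, chrom = region$chrom,
                 dosages = dosages),
            class = "genotype_matrix")
}

# GT strings ("0/1", "1|0", "./.", NA) -> ALT dosage; any "." allele -> NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) == 0L || any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }, numeric(1))
  names(lut) <- u
  out <- matrix(lut[as.vector(gt)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants on %s\n",
              length(x$sample_ids), length(x$variant_ids), x$chrom))
  invisible(x)
}

#' Pairwise r-squared between two dosage vectors
#'
#' The squared Pearson correlation of ALT-allele dosages over
#' pairwise-complete samples — the genotypic r2 convention of PLINK 1.9's
#' `--r2` (no haplotype phasing). Returns `NA` when fewer than 2 complete
#' pairs remain or when either vector has zero variance on the complete
#' pairs (e.g. a monomorphic variant).
#'
#' @param a,b Numeric dosage vectors of equal length (values 0/1/2, `NA`
#'   allowed).
#' @return r2 in `[0, 1]`, or `NA`.
#' @examples
#' compute_r2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0))  # 1: sign ignored
#' @export
compute_r2 <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("compute_r2: length mismatch (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  }
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 2L) {
    warning("compute_r2: fewer than 2 pairwise-complete samples",
            call. = FALSE)
    return(NA_real_)
  }
  x <- a[ok]; y <- b[ok]
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  min(1, max(0, (sxy * sxy) / (sxx * syy)))
}

#' LD of every panel variant with the index SNP
#'
#' @param genos A `genotype_matrix`.
#' @param index_id Variant id of the index SNP.
#' @param population Population label carried through to plots/reports.
#' @return An `ld_result`: list with `index_id`, `population`,
#'   `index_in_panel`, and `r2` — a named vector with one entry per panel
#'   variant (`NA` where r2 is undefined). If the index SNP is absent from
#'   the panel the result is flagged and all entries are `NA`; downstream
#'   plotting falls back to the "missing" color rather than aborting.
#' @export
ld_to_index <- function(genos, index_id, population = "ALL") {
  vids <- genos$variant_ids
  r2 <- stats::setNames(rep(NA_real_, length(vids)), vids)
  in_panel <- index_id %in% vids
  if (!in_panel) {
    warning(sprintf(
      "ld_to_index: index SNP '%s' absent from genotype panel; all r2 missing",
      index_id), call. = FALSE)
  } else if (length(vids) > 0L) {
    a <- genos$dosages[, index_id]
    for (vid in vids) {
      r2[[vid]] <- suppressWarnings(compute_r2(a, genos$dosages[, vid]))
    }
  }
  structure(list(index_id = index_id, population = population,
                 index_in_panel = in_panel, r2 = r2),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> index %s (%s), %d variants, %d missing r2\n",
              x$index_id, x$population, length(x$r2), sum(is.na(x$r2))))
  invisible(x)
}

#' LD bin labels used for point coloring
#' @return Character vector of the five r2 bins plus `"missing"`, in order.
#' @export
ld_bin_levels <- function() {
  c("0.0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1.0", "missing")
}

#' Assign r-squared values to color bins
#'
#' Five equal-width bins with left-closed edges
#' `[0,0.2) [0.2,0.4) [0.4,0.6) [0.6,0.8) [0.8,1.0]`; `NA` maps to
#' `"missing"`. The index SNP gets its distinct marker upstream, not here.
#'
#' @param r2 Numeric vector in `[0, 1]`, `NA` allowed.
#' @return Character vector of bin labels (see [ld_bin_levels()]).
#' @export
assign_ld_bin <- function(r2) {
  bad <- !is.na(r2) & (r2 < 0 | r2 > 1)
  if (any(bad)) {
    stop(sprintf("assign_ld_bin: r2 outside [0, 1]: %s",
                 paste(utils::head(r2[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  labs <- ld_bin_levels()
  idx <- pmin(findInterval(r2, c(0, 0.2, 0.4, 0.6, 0.8)), 5L)
  out <- labs[idx]
  out[is.na(r2)] <- "missing"
  out
}

#' Smallest region spanned by SNPs in LD with the index
#'
#' The tightest interval containing every SNP with `r2 >= cutoff` (missing
#' r2 excluded), converted to 0-based half-open. The index SNP always
#' qualifies, so the region always contains the index position; if nothing
#' else qualifies the result degenerates to a 1-bp interval at the index
#' (with a warning).
#'
#' @param ld An `ld_result` containing the index.
#' @param positions Named numeric vector: variant id -> 1-based position.
#' @param cutoff r2 cutoff in (0, 1].
#' @param chrom Chromosome of the returned interval.
#' @return A [genomic_interval()].
#' @export
ld_cutoff_region <- function(ld, positions, cutoff, chrom) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= 0 || cutoff > 1) {
    stop("ld_cutoff_region: cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (!ld$index_id %in% names(positions)) {
    stop(sprintf("ld_cutoff_region: index SNP '%s' has no position",
                 ld$index_id), call. = FALSE)
  }
  r2 <- ld$r2[names(positions)]
  qualify <- names(positions)[!is.na(r2) & r2 >= cutoff]
  qualify <- union(qualify, ld$index_id)
  if (length(qualify) == 1L) {
    warning(sprintf(
      "ld_cutoff_region: no SNP other than the index reaches r2 >= %g; 1-bp region",
      cutoff), call. = FALSE)
  }
  pos <- positions[qualify]
  genomic_interval(chrom, min(pos) - 1, max(pos))
}
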