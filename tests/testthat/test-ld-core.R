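test_that("compute_r2 handles identical, opposite and frozen-oracle vectors", {
  expect_equal(compute_r2(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1)), 1.0)
  # perfect negative correlation still gives r2 = 1
  expect_equal(compute_r2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0)), 1.0)
  # frozen value from the sum-formula Pearson oracle
  expect_equal(compute_r2(c(0, 1, 2, 2, 1, 0, 1, 2),
                          c(0, 0, 1, 2, 1, 1, 0, 2)),
               0.41091387245233402, tolerance = 1e-14)
})

test_that("compute_r2 error and missing-value contract", {
  expect_error(compute_r2(c(0, 1), c(0, 1, 2)), "length mismatch")
  expect_warning(r <- compute_r2(c(0, NA, NA), c(NA, 1, 2)),
                 "fewer than 2")
  expect_true(is.na(r))
  # zero variance on the complete pairs -> missing, not 0
  expect_true(is.na(compute_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
})

test_that("compute_r2 agrees with cor()^2 over pairwise-complete samples", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(10:500, 1)
    a <- random_dosages(n, miss_prob = 0.1)
    b <- random_dosages(n, miss_prob = 0.1)
    ours <- suppressWarnings(compute_r2(a, b))
    oracle <- suppressWarnings(
      stats::cor(a, b, use = "pairwise.complete.obs")^2)
    if (is.na(ours)) {
      expect_true(is.na(oracle) || sum(!is.na(a) & !is.na(b)) < 2)
    } else {
      expect_equal(ours, oracle, tolerance = 1e-12)
    }
  }
})

test_that("r2 is symmetric, affine-invariant and bounded in [0, 1]", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(5:100, 1)
    a <- random_dosages(n, miss_prob = 0.05)
    b <- random_dosages(n, miss_prob = 0.05)
    r_ab <- suppressWarnings(compute_r2(a, b))
    r_ba <- suppressWarnings(compute_r2(b, a))
    expect_identical(is.na(r_ab), is.na(r_ba))
    if (!is.na(r_ab)) {
      expect_equal(r_ab, r_ba, tolerance = 1e-14)
      expect_gte(r_ab, 0); expect_lte(r_ab, 1)
      # allele flip (b -> 2 - b) and general affine recoding
      expect_equal(suppressWarnings(compute_r2(a, 2 - b)), r_ab,
                   tolerance = 1e-12)
      slope <- sample(c(-3, -0.5, 0.25, 2), 1)
      expect_equal(suppressWarnings(compute_r2(a, slope * b + 1)), r_ab,
                   tolerance = 1e-10)
    }
  }
})

test_that("ld_to_index covers every variant and flags an absent index", {
  cfg <- sim_config(n_samples = 60, n_snps = 5, block_size = 5, seed = 9)
  genos <- simulate_genotypes(cfg)
  ld <- ld_to_index(genos, genos$variant_ids[1], "EUR")
  expect_length(ld$r2, 5)
  expect_named(ld$r2, genos$variant_ids)
  expect_equal(unname(ld$r2[[1]]), 1.0)
  expect_equal(ld$population, "EUR")

  # monomorphic variant gets a missing (not zero) entry
  genos$dosages[, 3] <- 2
  ld2 <- ld_to_index(genos, genos$variant_ids[1])
  expect_true(is.na(ld2$r2[[3]]))

  # permuting sample order leaves the result unchanged
  perm <- sample(nrow(genos$dosages))
  genos_p <- genos
  genos_p$dosages <- genos$dosages[perm, ]
  genos_p$sample_ids <- genos$sample_ids[perm]
  expect_equal(ld_to_index(genos_p, genos$variant_ids[1])$r2, ld2$r2)

  expect_warning(ld3 <- ld_to_index(genos, "rs_absent"), "absent")
  expect_false(ld3$index_in_panel)
  expect_true(all(is.na(ld3$r2)))
})

test_that("LD bins use left-closed 0.2-wide edges and a missing label", {
  expect_equal(assign_ld_bin(0.85), "0.8-1.0")
  expect_equal(assign_ld_bin(0.2), "0.2-0.4")   # left-closed edges
  expect_equal(assign_ld_bin(NA), "missing")
  expect_equal(assign_ld_bin(c(0, 0.19, 0.4, 0.6, 0.79, 0.8, 1)),
               c("0.0-0.2", "0.0-0.2", "0.4-0.6", "0.6-0.8", "0.6-0.8",
                 "0.8-1.0", "0.8-1.0"))
  expect_error(assign_ld_bin(1.2), "outside")
  expect_error(assign_ld_bin(-0.1), "outside")
})

test_that("ld_cutoff_region spans qualifying SNPs and keeps the index", {
  ld <- structure(list(index_id = "p100", population = "ALL",
                       index_in_panel = TRUE,
                       r2 = c(p100 = 0.9, p200 = 0.3, p300 = 0.7)),
                  class = "ld_result")
  positions <- c(p100 = 100, p200 = 200, p300 = 300)
  r <- ld_cutoff_region(ld, positions, 0.5, "chr1")
  expect_equal(c(r$start, r$end), c(99, 300))

  # full span when everything qualifies
  ld_all <- ld; ld_all$r2[] <- 1.0
  positions5 <- c(p100 = 100, p200 = 200, p300 = 500)
  names(ld_all$r2) <- names(positions5)
  ld_all$index_id <- "p100"
  r_all <- ld_cutoff_region(ld_all, positions5, 1.0, "chr1")
  expect_equal(c(r_all$start, r_all$end), c(99, 500))

  # degenerate: only the index qualifies -> 1-bp interval with warning
  ld_solo <- ld; ld_solo$r2 <- c(p100 = 1.0, p200 = 0.1, p300 = NA)
  expect_warning(r1 <- ld_cutoff_region(ld_solo, positions, 1.0, "chr1"),
                 "1-bp")
  expect_equal(c(r1$start, r1$end), c(99, 100))
  expect_true(interval_contains_pos(r1, 100))
})

test_that("ld_cutoff_region is monotone in the cutoff and contains the index", {
  set.seed(303)
  for (i in 1:30) {
    m <- sample(5:40, 1)
    ids <- sprintf("v%d", seq_len(m))
    pos <- sort(sample.int(1e6, m))
    names(pos) <- ids
    r2 <- runif(m); r2[sample(m, max(1, m %/% 5))] <- NA
    idx <- sample(ids[!is.na(r2)], 1)
    r2[idx] <- 1.0
    ld <- structure(list(index_id = idx, population = "ALL",
                         index_in_panel = TRUE, r2 = r2),
                    class = "ld_result")
    cuts <- sort(runif(4, 0.05, 1))
    regions <- lapply(cuts, function(ct)
      suppressWarnings(ld_cutoff_region(ld, pos, ct, "chr1")))
    for (k in seq_along(cuts)) {
      expect_true(interval_contains_pos(regions[[k]], pos[[idx]]))
      if (k > 1) expect_true(interval_within(regions[[k]], regions[[k - 1]]))
    }
  }
})

test_that("VCF extraction windows, subsets, and skips non-SNVs", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:4)), collapse = "\t"),
    "chr1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "chr1\t150\trsB\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t200\trsC\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t250\trsD\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0\t0/1",
    "chr1\t900\trsE\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1\t0/0")
  f <- write_tmp(lines, ".vcf")
  region <- genomic_interval("chr1", 0, 500)
  expect_warning(g <- extract_genotypes(f, region), "skipped 2")
  expect_equal(g$variant_ids, c("rsA", "rsD"))       # region + SNV filter
  expect_equal(g$pos0, c(99, 249))
  expect_equal(unname(g$dosages[, "rsA"]), c(0, 1, 2, NA))  # ./. -> NA
  expect_equal(unname(g$dosages[, "rsD"]), c(1, 2, 0, 1))   # phased ok

  gs <- suppressWarnings(extract_genotypes(f, region, samples = c("S2", "S4")))
  expect_equal(gs$sample_ids, c("S2", "S4"))
  expect_equal(nrow(gs$dosages), 2L)
  expect_error(suppressWarnings(extract_genotypes(f, region, "nope")),
               "unknown sample")

  empty <- genomic_interval("chr1", 300, 400)
  expect_warning(g0 <- extract_genotypes(f, empty), "no biallelic")
  expect_length(g0$variant_ids, 0)
})
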