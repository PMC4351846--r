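# shared helpers: tiny on-disk fixtures built in code

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

tiny_summary_file <- function() {
  write_tmp(c("SNP CHR POS P",
              "rs1 1 100 0.5",
              "rs2 1 50 0.01"))
}

# small track of interval features for overlap tests
random_interval_track <- function(n, region, label = "rand") {
  s <- sample(seq(region$start, region$end - 2), n, replace = TRUE)
  w <- sample(1:2000, n, replace = TRUE)
  new_track(label, "intervals", features = data.frame(
    chrom = region$chrom, start = s, end = pmin(s + w, region$end),
    name = sprintf("f%d", seq_len(n)), value = seq_len(n),
    strand = ".", color = NA_character_, stringsAsFactors = FALSE))
}

# random dosage vector with optional missingness
random_dosages <- function(n, miss_prob = 0) {
  d <- sample(0:2, n, replace = TRUE)
  if (miss_prob > 0) d[stats::runif(n) < miss_prob] <- NA
  d
}

# sweep-line maximum overlap depth over half-open intervals (layout oracle)
max_overlap_depth <- function(start, end) {
  ev <- rbind(data.frame(x = start, d = 1), data.frame(x = end, d = -1))
  ev <- ev[order(ev$x, ev$d), ]   # ends (-1) before starts (+1) at same x
  max(cumsum(ev$d))
}

# shared synthetic locus on disk, built once per test run
fixture_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "locusviz-fixture")
      cache <<- write_fixture_locus(d, sim_config(seed = 20240915))
    }
    cache
  }
})
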