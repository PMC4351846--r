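test_that("BED parsing: verbatim half-open coordinates, fields, headers", {
  f <- write_tmp("chr1\t100\t200", ".bed")
  tr <- parse_bed(f)
  expect_equal(tr$kind, "intervals")
  expect_equal(tr$features$start, 100)
  expect_equal(tr$features$end, 200)

  # BED9 itemRgb -> feature color
  f9 <- write_tmp("chr1\t100\t200\tfeat\t900\t+\t100\t200\t255,0,0", ".bed")
  tr9 <- parse_bed(f9)
  expect_equal(unname(grDevices::col2rgb(tr9$features$color)[, 1]),
               c(255, 0, 0))
  expect_equal(tr9$features$name, "feat")
  expect_equal(tr9$features$value, 900)

  # track header line skipped
  fh <- write_tmp(c("track name=\"x\" description=\"y\"",
                    "chr1\t10\t20", "chr1\t30\t40"), ".bed")
  expect_equal(nrow(parse_bed(fh)$features), 2L)
})

test_that("malformed interval files raise format errors, never crash", {
  expect_error(parse_bed(write_tmp("chr1\t200\t100", ".bed")), "format error")
  expect_error(parse_bed(write_tmp("chr1\t100\t100", ".bed")),
               "end <= start")
  expect_error(parse_bed(write_tmp("chr1\tabc\t200", ".bed")), "format error")
  expect_error(parse_wiggle(write_tmp("5.5", ".wig")), "format error")
  expect_error(parse_wiggle(write_tmp(
    c("fixedStep chrom=chr1 start=10 step=0", "1"), ".wig")), "format error")
  expect_error(parse_bedgraph(write_tmp("chr1\t10\tx\t1", ".bg")),
               "format error")
  expect_error(parse_gene_models(write_tmp(
    "chr1\t100\t500\tG\t0\t+\t100\t500\t0\t2\t50\t0,300", ".bed"), "bed12"),
    "format error")
})

test_that("WIG parsing: fixedStep/variableStep arithmetic and block merging", {
  f <- write_tmp(c("fixedStep chrom=chr1 start=101 step=10",
                   "1", "2", "3"), ".wig")
  tr <- parse_wiggle(f)
  expect_equal(tr$kind, "signal")
  expect_equal(tr$signal$start, c(100, 110, 120))   # 1-based -> 0-based
  expect_equal(tr$signal$value, c(1, 2, 3))

  fv <- write_tmp(c("variableStep chrom=chr1", "151 5.5"), ".wig")
  trv <- parse_wiggle(fv)
  expect_equal(trv$signal$start, 150)
  expect_equal(trv$signal$value, 5.5)

  # two declaration blocks concatenate with strictly increasing positions
  f2 <- write_tmp(c("variableStep chrom=chr1", "11 1.0", "21 2.0",
                    "variableStep chrom=chr1", "31 3.0"), ".wig")
  tr2 <- parse_wiggle(f2)
  expect_equal(tr2$signal$start, c(10, 20, 30))
  expect_true(all(diff(tr2$signal$start) > 0))
})

test_that("bedGraph parsing: steps, overlap rejection, sort-with-warning", {
  f <- write_tmp("chr1\t0\t10\t2.0", ".bg")
  tr <- parse_bedgraph(f)
  expect_equal(tr$signal$start, 0)
  expect_equal(tr$signal$end, 10)
  expect_equal(tr$signal$value, 2)

  f2 <- write_tmp(c("chr1\t0\t10\t2.0", "chr1\t10\t20\t3.0"), ".bg")
  expect_equal(nrow(parse_bedgraph(f2)$signal), 2L)   # adjacent is legal

  fo <- write_tmp(c("chr1\t0\t10\t2.0", "chr1\t5\t15\t3.0"), ".bg")
  expect_error(parse_bedgraph(fo), "overlapping")

  fu <- write_tmp(c("chr1\t50\t60\t1.0", "chr1\t0\t10\t2.0"), ".bg")
  expect_warning(tru <- parse_bedgraph(fu), "out of order")
  expect_equal(tru$signal$start, c(0, 50))
})

test_that("gene models parse from BED12 and GFF3 with coordinate conversion", {
  fb <- write_tmp("chr1\t100\t500\tGENE1\t0\t+\t100\t500\t0\t2\t50,100\t0,300",
                  ".bed")
  gm <- parse_gene_models(fb, "bed12")
  expect_length(gm, 1)
  g <- gm[[1]]
  expect_equal(g$name, "GENE1")
  expect_equal(g$strand, "+")
  expect_equal(c(g$tx$start, g$tx$end), c(100, 500))
  expect_equal(g$exons$start, c(100, 400))
  expect_equal(g$exons$end, c(150, 500))

  fg <- write_tmp(c(
    "##gff-version 3",
    "chr1\t.\tgene\t101\t500\t.\t-\t.\tID=gene1;Name=G1",
    "chr1\t.\tmRNA\t101\t500\t.\t-\t.\tID=tx1;Parent=gene1",
    "chr1\t.\texon\t101\t150\t.\t-\t.\tParent=tx1",
    "chr1\t.\texon\t401\t500\t.\t-\t.\tParent=tx1"), ".gff3")
  gg <- parse_gene_models(fg, "gff3")
  expect_length(gg, 1)
  expect_equal(gg[[1]]$strand, "-")
  expect_equal(c(gg[[1]]$tx$start, gg[[1]]$tx$end), c(100, 500))  # 1-based in
  expect_equal(gg[[1]]$exons$start, c(100, 400))

  fe <- write_tmp(c("##gff-version 3",
                    "chr1\t.\texon\t101\t150\t.\t+\t."), ".gff3")
  expect_error(parse_gene_models(fe, "gff3"), "format error")
})

test_that("genetic map parsing and interpolation", {
  f <- write_tmp(c("Position(bp)\tRate(cM/Mb)\tMap(cM)",
                   "100\t0.5\t0", "200\t2.0\t0.000125", "300\t0.1\t0.00023"))
  map <- parse_genetic_map(f)
  expect_equal(nrow(map), 3L)
  expect_equal(recomb_rate_at(map, 200), 2.0)          # node hit
  expect_equal(recomb_rate_at(map, 150), 1.25)         # linear midpoint
  expect_equal(recomb_rate_at(map, 50), 0.5)           # left extrapolation
  expect_equal(recomb_rate_at(map, 1e6), 0.1)          # right extrapolation

  fu <- write_tmp(c("pos rate", "200 2.0", "100 0.5"))
  expect_warning(mu <- parse_genetic_map(fu), "out of order")
  expect_equal(mu$pos, c(100, 200))

  fd <- write_tmp(c("pos rate", "100 0.5", "100 0.9", "200 2.0"))
  expect_warning(md <- parse_genetic_map(fd), "duplicate")
  expect_equal(md$rate[md$pos == 100], 0.9)            # last value kept

  expect_error(parse_genetic_map(write_tmp(c("pos rate", "100 -1"))),
               "negative")
  expect_error(recomb_rate_at(data.frame(), 5), "empty")
})

test_that("recomb_rate_at matches an independent two-point interpolation", {
  oracle <- function(map, q) {
    if (q <= map$pos[1]) return(map$rate[1])
    n <- nrow(map)
    if (q >= map$pos[n]) return(map$rate[n])
    i <- max(which(map$pos <= q))
    w <- (q - map$pos[i]) / (map$pos[i + 1] - map$pos[i])
    (1 - w) * map$rate[i] + w * map$rate[i + 1]
  }
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    map <- data.frame(pos = sort(sample.int(1e6, n)),
                      rate = runif(n, 0, 60))
    class(map) <- c("genetic_map", "data.frame")
    qs <- c(sample.int(1.2e6, 20), map$pos[1], map$pos[n])
    expect_equal(recomb_rate_at(map, qs),
                 vapply(qs, oracle, numeric(1), map = map),
                 tolerance = 1e-10)
  }
})

test_that("features_in uses half-open overlap and equals brute force", {
  region <- genomic_interval("chr1", 150, 300)
  tr <- new_track("t", "intervals", features = data.frame(
    chrom = "chr1", start = c(100, 100, 250), end = c(200, 150, 400),
    stringsAsFactors = FALSE))
  kept <- features_in(tr, region)$features
  expect_equal(kept$start, c(100, 250))   # touching [100,150) is dropped

  sig <- new_track("s", "signal", signal = data.frame(
    chrom = "chr1", start = c(100, 200, 300), end = c(101, 201, 301),
    value = 1:3))
  expect_equal(features_in(sig, genomic_interval("chr1", 150, 250))$signal$value, 2)

  set.seed(88)
  for (rep in 1:20) {
    reg <- genomic_interval("chr1", 1000, 50000)
    tr <- random_interval_track(40, genomic_interval("chr1", 0, 60000))
    got <- features_in(tr, reg)$features
    f <- tr$features
    want <- f[f$start < reg$end & f$end > reg$start, , drop = FALSE]
    expect_equal(got$name, want$name)
  }
})

test_that("track and gene-model writers round-trip through the parsers", {
  region <- genomic_interval("chr1", 0, 100000)
  sim <- simulate_tracks_and_genes(region, seed = 4)

  b <- tempfile(fileext = ".bed")
  write_track_bed(sim$tracks[[1]], b)
  back <- parse_bed(b, label = sim$tracks[[1]]$label)
  expect_equal(back$features[c("chrom", "start", "end", "name", "value")],
               sim$tracks[[1]]$features[c("chrom", "start", "end", "name",
                                          "value")])

  w <- tempfile(fileext = ".wig")
  write_track_wig(sim$tracks[[2]], w)
  backw <- parse_wiggle(w, label = sim$tracks[[2]]$label)
  expect_equal(backw$signal, sim$tracks[[2]]$signal)

  bg <- tempfile(fileext = ".bg")
  write_track_bedgraph(sim$tracks[[2]], bg)
  backbg <- parse_bedgraph(bg, label = sim$tracks[[2]]$label)
  expect_equal(backbg$signal, sim$tracks[[2]]$signal)

  # chromatin-state track keeps names and colors through BED9
  s <- tempfile(fileext = ".bed")
  write_track_bed(sim$tracks[[3]], s)
  backs <- parse_bed(s)
  expect_equal(backs$features$name, sim$tracks[[3]]$features$name)
  expect_equal(toupper(backs$features$color),
               toupper(sim$tracks[[3]]$features$color))

  g12 <- tempfile(fileext = ".bed")
  write_gene_models_bed12(sim$genes, g12)
  backg <- parse_gene_models(g12, "bed12")
  expect_length(backg, length(sim$genes))
  for (i in seq_along(backg)) {
    expect_equal(backg[[i]]$name, sim$genes[[i]]$name)
    expect_equal(backg[[i]]$strand, sim$genes[[i]]$strand)
    expect_equal(backg[[i]]$tx, sim$genes[[i]]$tx)
    expect_equal(backg[[i]]$exons, sim$genes[[i]]$exons)
  }

  m <- tempfile(fileext = ".txt")
  write_genetic_map(sim$map, m)
  backm <- parse_genetic_map(m)
  expect_equal(backm$pos, sim$map$pos)
  expect_equal(backm$rate, sim$map$rate, tolerance = 1e-12)
})
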