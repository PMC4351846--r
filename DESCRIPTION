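Package: locusviz
Title: Regional GWAS Plots with Linkage Disequilibrium and Genomic
    Annotation Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Renders multi-panel regional plots of genome-wide association
    study (GWAS) results: an association scatter with per-SNP linkage
    disequilibrium (r2) coloring and a recombination-rate overlay, gene
    models with collision-free symbol placement, one to ten genomic
    annotation tracks (BED, bedGraph, WIG), and an optional zoom panel
    defined by an r2 cutoff or a magnification factor. Pairwise r2 against
    the index SNP is computed natively from VCF genotype dosages (squared
    Pearson correlation over pairwise-complete samples). Each locus also
    yields a structured machine-readable annotation report (genes in the
    region, LD, overlapping track features) and every figure is accompanied
    by a layout manifest for programmatic inspection. A synthetic-data
    generator produces fully self-contained inputs (LD-block genotypes,
    association statistics, gene models, tracks, genetic maps) in the
    standard text formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
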