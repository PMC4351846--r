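---
title: "Methods: regional association plots, native LD, and locus annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional association plots, native LD, and locus annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusviz)
```

## The problem

A genome-wide association study yields one P-value per SNP. Interpreting a
significant locus requires seeing that signal in its genomic context: the
linkage disequilibrium (LD) structure that determines which variants are
statistically indistinguishable from the lead SNP, the recombination
hotspots that bound the associated haplotype, and the functional annotation
(genes, regulatory elements, chromatin state, conservation) that suggests
mechanism. `locusviz` assembles all of this into one multi-panel figure and
one machine-readable report per locus, computing LD natively from genotype
dosages instead of shelling out to an external tool.

## Coordinate conventions

Internally every interval is **0-based, half-open** (`[start, end)`), the
BED convention. The 1-based formats — summary-statistic positions, VCF, GFF3,
WIG — are converted once, at parse time. SNPs keep their 1-based `pos` as
data (it is what users see printed); the containment test against an
interval is `start <= pos - 1 < end`. A single arithmetic convention
everywhere removes the classic source of off-by-one drift when BED, GFF and
VCF inputs meet in one figure; touching intervals never overlap.

## Index SNP and window

The index SNP is the record with the smallest P-value, unless the user names
one. Ties (identical P) are broken by smallest position, then lexicographic
id — the choice is arbitrary but must be deterministic for reproducible
figures. The window is `pos ± flank_bp`, clamped at the chromosome origin;
the default flank of 500 kb is the conventional regional-plot window.
Summary rows with P outside (0, 1] are dropped and counted, not repaired:
P = 0 in particular has no −log10 image and almost always indicates an
underflow upstream that the user should know about.

## The r² estimator

For dosage vectors $g_i, g_j \in \{0,1,2\}^n$ (ALT-allele counts), we report
the squared Pearson correlation over pairwise-complete samples:

$$ r^2 = \frac{\left[\sum_k (g_{ik}-\bar g_i)(g_{jk}-\bar g_j)\right]^2}
              {\sum_k (g_{ik}-\bar g_i)^2 \sum_k (g_{jk}-\bar g_j)^2} $$

This is the *genotypic* r² — the default of PLINK 1.9's `--r2` — and needs
no haplotype phasing. The estimator is symmetric and invariant under allele
flips ($g \mapsto 2-g$) and any affine recoding with nonzero slope, which
the test suite asserts on randomized vectors, alongside agreement with
`cor()^2` to 1e-12. Design choices:

- **Missing genotypes** (`./.`) are removed pairwise per variant pair
  (pairwise-complete deletion), with a minimum of 2 complete pairs. This
  matches the correlation convention and keeps small panels usable.
- **Zero variance** (monomorphic variant on the complete pairs) yields a
  *missing* r², never 0 — "no information" and "no correlation" are
  different statements, and the plot shows them differently.
- The ratio is clamped to [0, 1] to absorb floating-point overshoot of at
  most a few ulp; self-correlation is exactly 1 by construction.
- If the index SNP is absent from the genotype panel, the run degrades
  gracefully: all points take the "missing" color and a warning is logged,
  rather than aborting the figure.

Only biallelic SNVs are taken from the VCF; multi-allelic sites and indels
are skipped with a logged count, since a single ALT-dosage column does not
represent them faithfully.

### LD bins

Five equal, left-closed bins — [0, 0.2), [0.2, 0.4), [0.4, 0.6),
[0.6, 0.8), [0.8, 1.0] — plus "missing", with a separate marker for the
index. The edges and palette follow the de-facto regional-plot convention;
both are configurable because neither is canonical.

## Recombination overlay

The genetic map (position, rate in cM/Mb) is linearly interpolated between
flanking points and **extrapolated as a constant** beyond its range: a map
that stops mid-window should not produce an artificial cliff to zero at its
last point. The curve is sampled at 500 evenly spaced positions across the
window — finer than any visible feature at typical window sizes, and cheap.
Out-of-order map rows are sorted with a warning (real exports frequently
are), and duplicate positions collapse to the last value.

## Gene label layout

The gene panel must place glyph + symbol for every transcript with no
overlap, in as few rows as possible. Each gene's reserved *extent* is the
union of its transcript span and a label box of width
`nchar(name) × chars_to_bp` centered on the transcript midpoint, clipped to
the window; `chars_to_bp` defaults to window length / 120 characters of
panel capacity. Rows are then assigned by **greedy first-fit over extents
sorted by start** (ties: end, then name). For intervals processed in start
order, first-fit coloring is optimal: the number of rows equals the maximum
overlap depth of the extent set, which the tests verify against an
independent sweep-line oracle on randomized inputs. The algorithm is also
deterministic, which matters more here than marginal aesthetics.

## Tracks

A track is either interval features (with optional name, value, strand,
color — chromatin-state tracks are interval tracks whose name/color carry
the state) or a strictly increasing (position, value) signal. Parsing is
delegated to `rtracklayer` and validated on top of it: bedGraph overlap is a
format error (the format forbids it), out-of-order records are sorted with a
warning, BED12 block arity is checked before import, and WIG declarations
with non-positive steps are rejected. Between 1 and 10 tracks are drawn per
figure; the optional SNP tick track shares its bin assignment and palette
with the association panel, so the two displays can never disagree. Tracks
come from local files only; there is no live genome-browser retrieval
(users can download any browser table and supply it as a custom track).

## Zoom panel

Two modes, both clipped to the main window and both guaranteed to contain
the index position:

- **factor k** (k > 1): length = window length / k (rounded), centered on
  the index. Near a window edge the zoom *shifts inward to preserve its
  length* rather than shrinking — a 5× zoom should stay a 5× zoom.
- **r² cutoff c**: the smallest interval containing every SNP with
  r² ≥ c. If only the index qualifies, the region degenerates to 1 bp with
  a warning. The region is monotone: raising the cutoff never enlarges it.

## The layout manifest

Pixel-level image comparison is brittle across font stacks and device
versions, so every figure is accompanied by a JSON manifest of its
geometry: panel order, per-SNP (x, y, bin, color), gene row assignments,
track lanes, and the zoom bounds. Point x-coordinates are the basepair
positions themselves (an affine map to device space happens inside the
device), so linearity, containment and completeness are directly
assertable. All determinism tests compare manifests, not pixels.

## The synthetic-data generator

The generator exists so that every parser and every stage of the pipeline
can be exercised end-to-end with no external data. Per sample it draws two
haplotypes; within each LD block of `block_size` SNPs a haplotype copies a
block-ancestral allele (frequency 0.5) and flips each SNP independently
with probability `within_block_flip_prob` (default 0.05); blocks are
independent; dosage is the haplotype sum. A continuous phenotype
`y = effect × dosage(causal) + N(0,1)` gives per-SNP P-values from the
closed-form t test of the simple-regression slope on n − 2 df
(monomorphic variants get P = 1). Tracks, 3–8 gene models with 1–5 exons,
and a genetic map with one Gaussian-bump hotspot are drawn inside the
region, and everything is written to real files — VCF, BED, BED12, WIG,
bedGraph, map tables — so tests parse independently written text rather than
in-memory objects.

What it emulates: block-structured LD with tunable decay, a causal signal
whose strongest association lands in the causal block, uniform null
P-values, and realistic file dialects. What it does **not** emulate:
coalescent genealogies, realistic allele-frequency spectra, LD decay within
blocks by distance, population structure or relatedness, genotyping error,
or imputation uncertainty. Passing tests therefore validate the *machinery*
(LD arithmetic, windowing, parsing, layout, reporting) — they are not
evidence about any real locus.

The standard study conditions used across the test suite are 500 samples ×
200 SNPs in 1 Mb, 20-SNP blocks, flip probability 0.05, effect 1.0, fixed
seeds; the null-calibration check uses 200 SNPs at effect 0. The
Kolmogorov–Smirnov uniformity diagnostic in the acceptance script uses
independent SNPs (block size 1), because with 20-SNP blocks the 200
P-values carry only ~10 effective degrees of freedom and the KS statistic
becomes noisy without indicating miscalibration.

## Numerical and degenerate-input choices

- P = 0 rows: rejected with a counted warning (see above).
- r² of constant vectors, or < 2 complete pairs: missing, with a warning.
- LD-cutoff region with no qualifying SNP beyond the index: 1-bp interval
  at the index, warning.
- Empty VCF region: a valid zero-variant matrix plus warning; the caller
  (pipeline) renders uncolored points rather than failing.
- Duplicate summary rows (same chrom, pos, id): dropped, counted.
- Genetic map with a single point: constant rate everywhere.
- Layout ties: start, then end, then name — identical inputs always give
  identical figures.

## Limitations

- Genotypic r² only; haplotype-phase (EM) r², D′ and multi-index
  conditional LD are out of scope.
- Text formats only: bigWig/bigBed are not read (convert to WIG/bedGraph).
- One chromosome per figure; the window is a single interval.
- The label-width model is character-count based, not font-metric based;
  extreme aspect ratios may pack labels tighter than optimal visually
  (never overlapping — the extent guarantees that).
- VCFs are read whole and then windowed; for very large reference panels a
  region-indexed reader would be preferable.
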