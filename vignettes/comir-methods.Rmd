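---
title: "Methods: paired single-cell miRNA/mRNA co-profiling with comir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired single-cell miRNA/mRNA co-profiling with comir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comir)
```

## Overview

`comir` implements the computational side of a dual-library single-cell
assay in which each cell yields two sequencing libraries — one for small
RNAs (chiefly miRNAs) and one for mRNA — sharing the same dual-index cell
barcodes and unique molecular identifiers (UMIs). The package covers four
stages:

1. **Read demultiplexing**: slicing raw reads into barcode, UMI and
   insert; correcting barcodes against a whitelist; trimming the
   small-RNA 3' adapter.
2. **Quantification**: collapsing UMIs with one-mismatch adjacency and
   building multimapper-weighted cell × feature matrices.
3. **Co-inertia integration**: a two-table ordination of paired miRNA and
   mRNA group profiles with the RV coefficient, quadrant assignment and
   miRNA-target overlays.
4. **Group statistics**: marker-rule subpopulation classification and
   Wilcoxon rank-sum condition comparisons with Bonferroni correction.

A seeded synthetic generator (`synthetic_scenario()`,
`simulate_expression()`, `simulate_reads()`) produces data with the exact
structural assumptions above plus ground truth, so every stage is
verifiable without external data.

## Read structure and demultiplexing

A `read_layout()` declares where the barcode and UMI live (0-based,
half-open); the insert is everything after the last structural segment.
Cells are identified by a *dual-index* barcode: two short index reads
concatenated into one logical barcode string, so matching reduces to a
single whitelist lookup.

Barcode correction accepts the unique whitelist entry within Hamming
distance 1 (exact matches win immediately). The tolerance is not part of
the assay definition; Hamming ≤ 1 with a uniqueness requirement is the
standard choice for short synthetic barcodes, and ambiguous reads — two
or more whitelist entries at the minimal distance — are never assigned.
With indices designed at pairwise Hamming distance ≥ 3, a single
substitution can never flip one valid barcode into another's
neighbourhood, which is why the demultiplexing accuracy on correctable
reads is effectively perfect in the synthetic runs.

Small-RNA inserts end in a 3' adapter. Trimming removes the suffix at the
leftmost occurrence of an adapter prefix of length ≥ 5 with at most one
mismatch (both configurable). Reads without an adapter occurrence are
flagged `untrimmed` and excluded from small-RNA quantification: a mature
miRNA is shorter than the read, so an untrimmed insert cannot match the
reference anyway. Every read ends in exactly one status class
(`assigned`, `unassigned_barcode`, `ambiguous_barcode`, `too_short`,
`untrimmed`), and the class counts always sum to the input count.

`downsample_reads()` draws exactly `min(n, total)` reads uniformly
without replacement under a private seeded RNG stream. Because the tagged
table is held in memory, a plain `sample.int()` draw is used rather than
a streaming reservoir; the contract (deterministic for a given seed and
input order) is the same.

## UMI collapsing and multimapper weighting

Reads sharing a UMI, or UMIs at Hamming distance 1, are treated as one
molecule: `collapse_umis()` builds the Hamming-1 graph over observed UMIs
and counts connected components (the symmetric "cluster" reading of
adjacency collapse; distance 0 — identical UMIs only — is available and
never yields fewer molecules). Each component is represented by its
lexicographically smallest member.

Collapsing is scoped per (cell, feature-set) group: single-mapped reads
collapse within their (cell, gene), and multimapped reads within their
(cell, identical feature set). Collapsing per cell globally would merge
legitimately reused UMIs across genes; per-gene scoping is the common
practice in UMI counting tools.

Each collapsed UMI contributes **unit mass split as 1/k across the k
features it maps to** (`weighting = "fractional"`). This preserves total
library mass: the raw matrix total equals the number of collapsed UMIs
exactly, which the tests assert at 1e-9. The literal alternative —
multiplying each UMI by its mapped-location count — inflates counts with
multimapping depth and is available as `weighting = "multiply"` for
comparison.

Normalization is a two-state machine recorded on the matrix:
`normalize_lognorm()` maps raw values to `ln(1 + v * 10000 / cell_total)`
(the convention of mainstream single-cell toolkits; scale factor
configurable), and re-normalizing an already normalized matrix is an
error rather than a silent double transform. Aggregated profiles use
`log2(1 + v * 1e6 / total)` (log2-RPM); the pseudocount of 1 keeps zeros
at zero in both transforms.

## Co-inertia analysis

Given group-averaged profiles `X` (groups × miRNA) and `Y` (groups ×
mRNA) on the same groups, columns are centered (optionally scaled) and
the axes come from the SVD of the cross-product `Xc' Yc`. Eigenvalues are
squared singular values; each table's rows are projected onto the common
axes, giving paired coordinates per group. Row weights are uniform:
profiles are averaged per cell type first, so each group is one row.

The RV coefficient is the standard matrix correlation

\[
RV = \frac{\lVert Y_c' X_c \rVert_F^2}
          {\lVert X_c' X_c \rVert_F \, \lVert Y_c' Y_c \rVert_F} \in [0, 1],
\]

whose numerator equals the total co-inertia (the eigenvalue sum). A
commonly printed verbal form of this formula ("total inertia divided by
the square root of the product of the squared total inertias") is
dimensionally inconsistent if read literally; the standard definition
above is what is implemented and tested against an independent
trace-formula oracle.

Two genuinely open choices were settled as follows:

* **Preprocessing.** Column-centered (PCA-style) duality is the default,
  with unit-variance scaling as an option. Correspondence-analysis
  variants exist in the ordination literature, but centered PCA is the
  transparent default for log-scale expression profiles and makes the
  eigenstructure directly comparable to a dense SVD oracle.
* **Axis signs.** The SVD sign indeterminacy is fixed by making the
  largest-magnitude miRNA loading on each axis positive, so coordinates
  are reproducible across LAPACK builds.

Quadrants follow the sign pattern (+,+) → Q1, (−,+) → Q2, (−,−) → Q3,
(+,−) → Q4 with zero counted as positive — an arbitrary but deterministic
tie rule. When four group centroids occupy four distinct quadrants,
quadrants can be renamed after the groups. `target_overlay()` places a
miRNA's predicted targets (from `consensus_targets()`, which keeps pairs
supported by ≥ 3 prediction algorithms by default) into the quadrants of
the mRNA loading plane; targets absent from the fitted matrix are tallied
as missing rather than erroring, since top-n feature selection routinely
drops weakly expressed targets.

Feature selection before ordination keeps the top 200 miRNAs and top
2500 mRNAs by total expression across groups (ties broken
lexicographically), matching standard practice for this analysis.

## Marker classification and group comparisons

`classify_by_markers()` implements an ordered marker-rule panel. The
default rules are the conserved lung panel: miR-142+miR-150 → lymphoid,
miR-142+miR-223 → myeloid, miR-126 → endothelial, miR-199 → stromal,
miR-200 → epithelial, miR-375 → alveolar, and cells with any miR-135b
expression (tumor cells) are removed before assignment. The assay gives
no numeric cutoffs, so the defaults are the weakest sensible ones — any
nonzero normalized exclusion-marker expression removes a cell, and a
label is assigned when its mean marker expression is the maximum and
positive — with both thresholds exposed in `marker_rule_set()`.

`compare_groups()` performs one two-sided Wilcoxon rank-sum test per
(subpopulation, miRNA) between two condition groups. The p-value is exact
by enumeration when the combined sample size is ≤ 12 without ties,
otherwise a normal approximation with tie and continuity correction is
used (delegated to `stats::wilcox.test`, whose switch matches this
contract). Bonferroni correction is applied over **all tests performed**,
not per subpopulation — the conservative reading when the correction
scope is unstated. Stars follow adjusted p < 0.001 (`***`), < 0.01
(`**`), < 0.1 (`*`). `split_by_median_age()` assigns samples above the
median age to `old` and below to `young`; a sample exactly at the median
goes to `old`, a deterministic rule needed for odd sample counts (e.g.
ages 42/57/63/70/76 → young = {42, 57}, old = {63, 70, 76}).

## The synthetic generator

`synthetic_scenario()` fixes the study conditions; its defaults emulate a
four-type cell mixture at desk scale:

* 4 types × 100 cells; per-cell molecule counts log-normal (median 250
  small-RNA, 500 mRNA molecules), totalling roughly 100K small-RNA and
  200K mRNA reads — the depth regime of the standard subsample presets.
* 220 miRNAs and 2600 mRNAs, so the prescribed top-200/top-2500
  selection actually truncates.
* Negative-binomial counts (dispersion 2) around per-type programs:
  a shared heavy-tailed baseline (gamma weights) with disjoint per-type
  signature blocks (25 miRNAs, 300 mRNAs) upregulated by per-type folds
  8/6/5/4. The folds differ on purpose: with equally distinctive types
  the co-inertia eigenvalues are nearly equal and the top-2D plane is
  rotationally degenerate, so which type contrast it captures is
  arbitrary — unlike real mixtures, where types differ in
  distinctiveness and the leading plane separates them stably.
* One planted repression link: the most expressed type-1 signature miRNA
  has 40 well-expressed non-signature mRNA targets whose means are
  multiplied by 0.25 in type 1. Attaching the link to a highly expressed
  miRNA reflects how focal miRNAs are chosen in practice (they must
  survive top-n selection to be plotted at all).
* A pool of 96 eight-nt indices at pairwise Hamming ≥ 3; each cell's
  barcode is an index pair concatenated (dual indexing), and the demux
  whitelist holds the in-use combinations.
* 0.5% per-base substitution error; 8 miRNA id pairs share a mature
  sequence (family multimapping for the small-RNA matcher); 5% of mRNA
  reads are reported at three locations covering two genes.

`simulate_reads()` emits one read per molecule, laid out
barcode + UMI + insert (+ adapter for small RNA), with truth tables
mapping every read to its cell, UMI and feature. Setting
`error_rate = 0`, `n_multimap_pairs = 0`, `mrna_multimap_rate = 0` and
`distinct_umis = TRUE` (UMIs pairwise Hamming ≥ 2 within each
(cell, feature) group) defines the *lossless limit*, in which the
pipeline provably reproduces the truth count matrix exactly — the
end-to-end identity test.

What the generator does **not** emulate: PCR duplication and chimeras,
ambient RNA, doublets, quality-score structure (qualities are constant),
indels, non-uniform coverage along transcripts, and empirical barcode
frequency skew. Passing tests therefore validate the pipeline's
bookkeeping and statistics under its stated assumptions, not robustness
to every artefact of real libraries.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on synthetic data at
desk scale: the default scenario (4 × 100 cells, ~310K reads total)
drives the demultiplexing, recovery and ordination checks; the lossless
scenario uses 4 × 80 cells; the marker scenario 7 × 60 cells. Oracle
checks use 50 random table pairs (co-inertia), 1000 random UMI multisets
(collapse), and full enumeration of rank arrangements up to combined
size 10 (Wilcoxon). Numerical tolerances: co-inertia eigenvalues and RV
against oracles at 1e-8, mass conservation at 1e-9, RV self-identity at
1e-12.

Degenerate inputs are rejected loudly: fewer than two groups, misaligned
rows, tables constant after centering (undefined RV), mixed UMI lengths,
zero-total profiles, empty groups in aggregation, and marker rules
referencing absent features are all errors naming the offender. Zero
coordinates in quadrant assignment and equal feature totals in top-n
selection are broken by stated deterministic rules (zero-as-positive;
lexicographic).

## Limitations

* The small-RNA matcher is a prefix matcher against a mature-miRNA
  reference with ≤ 1 substitution — deliberately simple, standing where a
  genome aligner would sit in a production run; mRNA quantification
  ingests external alignments rather than computing them.
* Co-inertia is computed on group-averaged profiles (one row per cell
  type), not per cell; it describes population-level correspondence.
* The RV coefficient on few groups with strong shared structure is close
  to 1 by construction; its value is most informative comparatively.
* Marker classification is a transparent rule panel, not a trained
  classifier; it presumes the marker panel is valid for the tissue.
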