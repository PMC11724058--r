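# comir

Processing and integrative analysis of **paired single-cell small-RNA and
mRNA sequencing libraries** — assays in which each cell yields both a
miRNA library and an mRNA library sharing dual-index cell barcodes and
UMIs. The package is aimed at bioinformaticians building or validating
such co-profiling pipelines: it covers everything between raw FASTQ and
the integrated miRNA–mRNA analysis, and ships a seeded synthetic
generator with ground truth so every stage can be verified without any
external dataset.

## What it computes

**Demultiplexing.** Reads are sliced into cell barcode, UMI and insert by
a declarative `read_layout()`. Barcodes are corrected against a whitelist
(unique match within Hamming distance ≤ 1; ambiguous reads are never
assigned), and small-RNA 3' adapters are trimmed at the leftmost
occurrence of an adapter prefix (overlap ≥ 5, ≤ 1 mismatch).

**UMI quantification.** Reads with the same or 1-mismatch-adjacent UMI
collapse into one molecule (connected components of the Hamming-1 graph,
scoped per cell and feature set). Each molecule contributes unit mass
split 1/k across the k features it maps to, so the total matrix mass
equals the number of molecules exactly. Normalization:
`ln(1 + v·10⁴/total)` per cell, or `log2(1 + v·10⁶/total)` (log2-RPM) for
aggregated profiles.

**Co-inertia integration.** For group-averaged profiles X (groups ×
miRNA) and Y (groups × mRNA), the ordination axes are the SVD of the
centered cross-product Xc′Yc; eigenvalues are squared singular values,
and the global similarity is the RV coefficient

    RV = ‖Yc′Xc‖²_F / (‖Xc′Xc‖_F · ‖Yc′Yc‖_F)  ∈ [0, 1].

The top 200 miRNAs / 2500 mRNAs by expression enter the analysis;
quadrants of the 2D plane correspond to group-specific expression, and a
miRNA's predicted targets (consensus of ≥ 3 prediction algorithms) are
overlaid to show whether they avoid the miRNA's own expression domain.

**Group statistics.** Marker-rule classification into six conserved
subpopulations (miR-142/miR-150 lymphoid, miR-142/miR-223 myeloid,
miR-126 endothelial, miR-199 stromal, miR-200 epithelial, miR-375
alveolar; miR-135b⁺ tumor cells removed), median-age condition splits,
and per-(subpopulation, miRNA) Wilcoxon rank-sum tests with Bonferroni
correction and star labels (adjusted p < 0.001/0.01/0.1 → `***`/`**`/`*`).

## Worked example

A synthetic four-type mixture, processed end to end and integrated:

```r
library(comir)

sc <- synthetic_scenario(n_cells_per_type = 25,
                         libsize_mirna = c(meanlog = log(120), sdlog = 0.3),
                         libsize_mrna = c(meanlog = log(150), sdlog = 0.3),
                         seed = 42)
sc
#> synthetic_scenario: 4 types x 25 cells, 220 miRNAs, 2600 mRNAs, error 0.005, seed 42

res <- run_end_to_end(sc)
#> demux: 12168 reads; assigned=12079 unassigned_barcode=32 untrimmed=57
#> demux: 16265 reads; assigned=16219 unassigned_barcode=46
#> assign_smallrna_features: 63/12079 reads unassigned
str(res$report)
#> List of 7
#>  $ barcode_accuracy  : num 1
#>  $ n_correctable     : int 28298
#>  $ ambiguous_assigned: int 0
#>  $ cor_mirna         : num 0.995
#>  $ cor_mrna          : num 0.991
#>  $ max_abs_diff_mirna: num 2.5
#>  $ max_abs_diff_mrna : num 1
```

Every read whose barcode was uniquely correctable landed in the true cell
(`barcode_accuracy = 1` over 28,298 reads), no ambiguous read was
assigned, and the recovered count matrices correlate with the simulated
truth at 0.995 (miRNA) and 0.991 (mRNA) despite 0.5% per-base sequencing
error and multimapping.

Integrating the paired truth profiles:

```r
truth <- res$truth
X <- select_top_expressed(
  aggregate_by_group(normalize_lognorm(truth$mirna), truth$labels), 200)
Y <- select_top_expressed(
  aggregate_by_group(normalize_lognorm(truth$mrna), truth$labels), 2500)
fit <- coinertia_fit(X, Y, k = 2)
fit
#> coinertia_result: 2 axes, 200 x 2500 features, RV = 0.9863
#> eigenvalues: 57940 27900 20700 6.204e-26 1.326e-26

m <- truth$links$mirna[1]          # the planted repressive miRNA
tg <- intersect(truth$links$target, rownames(fit$col_loadings_Y))
mean(fit$col_loadings_Y[tg, 1:2] %*% fit$col_loadings_X[m, 1:2] < 0)
#> [1] 0.8
```

The RV of 0.986 says the two modalities share almost all their group
structure (expected here: both carry the same four-type signatures), the
three positive eigenvalues reflect the rank limit of four groups, and
80% of the planted miRNA's repressed targets project into the half-plane
opposite the miRNA — the geometric signature of repression that the
target-overlay plots visualize. At the full default scenario size
(100 cells per type) this fraction reaches 100%.

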