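Package: comir
Title: Single-Cell miRNA and mRNA Co-Profiling Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and integrative analysis of paired single-cell small
    RNA and mRNA sequencing libraries. Extracts cell barcodes and unique
    molecular identifiers (UMIs) from raw reads, demultiplexes cells against a
    dual-index whitelist with mismatch correction, trims small-RNA 3' adapters,
    collapses UMIs with one-mismatch adjacency, and builds multimapper-weighted
    cell-by-feature expression matrices. Paired miRNA and mRNA group profiles
    are integrated by co-inertia analysis with the RV coefficient, quadrant
    assignment and miRNA target overlays; marker-rule classification and
    Wilcoxon rank-sum comparisons with Bonferroni correction support
    condition-group contrasts. A seeded synthetic read and expression
    simulator provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
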