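Package: clonalmem
Title: Clonal Epigenetic Memory Analysis from Lineage-Barcoded Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting clonally heritable epigenetic states in
    lineage-barcoded single-cell multi-omic experiments. Implements expressed
    lineage-barcode clone calling with two-stage Levenshtein collapse,
    background-corrected motif-family and gene-program deviation scoring,
    a permutation test for clonal heritability of per-cell scores,
    k-nearest-neighbour condition enrichment, transcription-factor co-binding
    scores from footprint changes, summit-based non-overlapping peak
    construction and pseudobulk utilities, and spatial tumor segmentation and
    program scoring. A synthetic-data module generates every input with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
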