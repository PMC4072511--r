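Package: intronsmith
Title: Intron-Mediated Tuning of Synthetic Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for intron-reporter expression libraries in
    budding yeast. Simulates plate-reader libraries with known ground truth,
    turns raw OD/fluorescence traces into splicing-efficiency indices
    (Butterworth low-pass filtering, background normalization, self-crossing
    signal-to-noise classification), computes intron and junction sequence
    features (sliding-window GC content and local RNA folding energy with a
    pluggable folding backend, splice-signal distances, motif scores,
    secondary-structure graph distances), discovers and localizes candidate
    splicing-regulatory motifs with hypergeometric enrichment and positional
    permutation nulls, and assembles a greedy linear predictor of expression
    with adjusted correlations, permutation significance and leakage-free
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    readr,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
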