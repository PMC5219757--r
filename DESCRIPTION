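Package: tfmodules
Title: Discovery of Combinatorial Transcription Factor Binding Modules
Version: 0.1.0
Authors@R: person("tfmodules", "developers", role = c("aut", "cre"),
    email = "tfmodules@example.org")
Description: Summarizes multi-factor in vivo binding data (ChIP-seq point
    calls) into combinable regulatory modules with a hierarchical Dirichlet
    process topic model fitted by collapsed Gibbs sampling.  Builds
    co-binding regions from pooled summit calls, learns a module-TF matrix
    and per-site module assignments, and provides the downstream analysis
    layers: z-score participation and main-driver calls, region module
    usage and multi-module census, module grouping and PCA, k-means and NMF
    baselines with a TF-TF correlation fidelity metric, direct versus
    indirect binding analysis with a random forest classifier, protein
    interaction rediscovery with a permutation test, epigenomic annotation
    overlap, cross-cell-type analysis, and a synthetic data generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    clue,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
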