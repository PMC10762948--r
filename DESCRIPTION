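Package: scDAbench
Title: Benchmarking Differential Abundance Testing for Multi-Sample
    Single-Cell Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates multi-sample single-cell datasets with known
    topology (linear and branching trajectories, discrete clusters),
    plants condition-specific differential-abundance (DA) effects with
    per-cell ground-truth labels, optionally injects batch effects in
    principal-component space, and benchmarks six re-implemented DA
    testing methods (Cydar-style hyperspheres, DA-seq-style multiscale
    logistic regression, Meld-style graph kernel density estimation,
    Cna-style neighborhood abundance matrices, Milo-style kNN
    neighborhoods with negative binomial models and spatial FDR, and
    Louvain cluster-level testing) with a percentile-threshold-sweep
    AUROC/AUPRC protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
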