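Package: fcgnn
Title: Ensemble Graph Neural Networks for Functional Connectome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-group classification of subjects from whole-brain functional
    connectivity. Builds Fisher-z functional-connectivity (FC) matrices from
    region-of-interest BOLD time series, sparsifies them into weighted
    k-nearest-neighbour graphs, and classifies subjects with three graph
    neural network base models (graph convolution, graph attention,
    neighbourhood-sampling aggregation) combined by a stacking ensemble
    meta-learner. Includes a stratified 10-fold cross-validation protocol
    with class-balance resampling (up-/down-sampling), ACC/SEN/SPE/AUC
    reporting, and a seeded synthetic-cohort generator so the full pipeline
    can be exercised without restricted clinical data. All layer operators,
    backpropagation and the Adam optimizer are implemented natively on
    sparse matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
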