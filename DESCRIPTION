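Package: choqfuzgcn
Title: Patient-Similarity Graph Convolutional Embeddings with Choquet
    Fuzzy-Integral Classifier Fusion for Survival Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies cancer patients as short-term (<5 years) or
    long-term survivors from multi-omics cohorts. Per-modality
    patient-similarity graphs are built by thresholding Pearson
    correlations between samples, node embeddings are learned with a
    semi-supervised graph convolutional network, the embeddings are
    stacked with clinical covariates, and three probabilistic base
    classifiers (logistic regression, RBF-kernel support vector machine,
    random forest) are fused with a Choquet fuzzy integral over a
    lambda-fuzzy (Sugeno) measure derived from validation accuracies.
    Includes mRMR feature selection, weighted k-nearest-neighbour
    imputation, SMOTE oversampling, stratified 10-fold evaluation, and a
    seeded synthetic multi-omics cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    glmnet,
    Matrix,
    methods,
    quadprog,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
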