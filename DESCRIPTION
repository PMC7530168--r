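Package: tlcnn
Title: Transfer-Learning CNN Prediction of Cognitive Outcome from Brain
    Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 2-year cognitive outcome of very preterm infants from
    term-equivalent-age brain structural connectomes (90x90 FA-weighted
    adjacency matrices). Implements a transfer-learning convolutional model:
    a frozen very-deep convolutional backbone used as a fixed feature
    extractor plus a trainable shallow convolutional head, trained with
    cross-entropy (high-risk classification) or mean-absolute-error
    (continuous score regression) losses. Ships the surrounding study
    machinery: a binned k-nearest-neighbour convex-combination oversampler
    for continuous labels, classical baselines (regularised linear models,
    support vector machines, fully connected and convolutional networks with
    optional unsupervised pre-training), repeated stratified five-fold
    cross-validation with percentile confidence intervals, Grad-CAM edge
    importance with anatomical naming, and a synthetic cohort generator with
    planted score-correlated edges so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr,
    e1071,
    glmnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
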