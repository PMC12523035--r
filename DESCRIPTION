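Package: riemnirs
Title: Riemannian-Geometry Classification of fNIRS Brain States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brain-state decoding for dual-chromophore functional
    near-infrared spectroscopy (fNIRS) on the manifold of symmetric
    positive-definite matrices. Estimates channel-by-channel kernel and
    covariance matrices per chromophore (HbO/HbR) with a registry of twelve
    estimators, regularizes them by shrinkage, and fuses them into
    block-diagonal "super kernel" features classified with tangent-space
    logistic regression or a Riemannian support vector classifier under the
    affine-invariant metric. Includes the full preprocessing chain (PCA
    global-component regression, band filtering, z-scoring, epoching), a
    synthetic fNIRS session generator for end-to-end testing, and the
    evaluation machinery: repeated stratified cross-validation, permutation
    chance estimation, bootstrap confidence intervals, relative improvement
    scores, and a Wasserstein comparison of HbO/HbR co-activation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    glmnet,
    randomForest,
    signal,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
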