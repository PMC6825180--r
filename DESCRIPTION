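Package: sdmjoint
Title: Joint and Single-Species Distribution Models for Presence-Background Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare a presence-background single-species
    distribution model (an L1-penalized maximum-entropy-style model) with a
    multivariate probit joint species distribution model (JSDM) fitted by
    Gibbs sampling. Includes occurrence cleaning (deduplication, spatial
    thinning, home-range buffering, background point sampling), synthetic
    landscape and community generation with known ground truth,
    probability-of-occurrence mapping, decomposition of pairwise species
    associations into environmental and residual correlations, and
    ROC/AUC plus threshold-based evaluation at multiple map resolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
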