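Package: eigenslopes
Title: Longitudinal Subspace Projection Features for Disease-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature construction for pattern recognition on longitudinal
    high-dimensional data such as structural neuroimaging biomarkers.
    Per-subject polynomial trajectories are fitted by least squares, the
    matrix of first-order (slope) coefficients is decomposed by PCA into
    "eigenslopes", and cross-sectional samples are projected onto the
    resulting low-rank subspace of common longitudinal change before linear
    support-vector classification. Includes within-set and
    information-transferring prediction with nested leave-one-out
    cross-validation over an explained-variance grid, permutation
    significance testing, classifier weight and covariance forward maps,
    mass-univariate t-maps, NIfTI mask handling, and a synthetic longitudinal
    cohort generator for balanced and unbalanced designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
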