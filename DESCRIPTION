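Package: osemeat
Title: Ordered-Subset EM CT Reconstruction and Epicardial Fat Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Iterative tomographic reconstruction by maximum-likelihood
    expectation maximization (MLEM) and its ordered-subset acceleration (OSEM)
    with angular-distance-optimized subset ordering, a Shepp-Logan phantom and
    parallel-beam projection simulator built on a sparse Siddon ray-tracing
    system matrix, Hounsfield-window epicardial adipose tissue (EAT) volumetry
    for CT volumes, Gensini coronary stenosis scoring with stenosed-vessel
    classification, and a calibrated synthetic-cohort simulator with the
    accompanying risk-factor statistics (logistic regression, Spearman
    correlation, ROC analysis, group comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
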