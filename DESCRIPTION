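Package: hfhisto
Title: Heart-Failure Histopathology Classification from Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-slide-image analysis pipeline that classifies patients as
    failing versus non-failing hearts from H&E-stained myocardial tissue.
    Provides seeded synthetic histology cohorts for testing, Otsu tissue
    masking and non-overlapping region-of-interest sampling, patch extraction
    with rotation augmentation, a small fully-convolutional neural network
    (~13.5k parameters) with pixel-to-image-to-patient probability
    aggregation, an engineered texture-feature comparator (CHARM-style feature
    bank, mRMR selection, 1000-tree random forest), evaluation statistics
    (confusion metrics, ROC/AUC, Cohen's kappa, t and Kolmogorov-Smirnov
    tests), and consensus clustering for cluster-number selection and
    discovery of mislabeled patients.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
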