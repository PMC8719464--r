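Package: perceptcad
Title: Perceptive-Feature Computer-Aided Diagnosis of Breast Masses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided diagnosis pipeline for benign/malignant
    classification of breast masses on mammography. Quantifies BI-RADS
    mass descriptions (shape, margin sharpness, microlobulation,
    spiculation, density) into a five-dimensional code vector, trains a
    two-channel VGG-style convolutional network to regress those codes
    and exposes its 128-unit penultimate layer as perceptive features,
    classifies lesions with stepwise feature selection plus linear
    discriminant analysis fused over k-fold cross-validation models,
    and provides multi-reader multi-case (MRMC) observer-study
    analytics: per-reader ROC/AUC, reader-averaged AUC comparison with
    bootstrap inference, confusion-matrix reconstruction from printed
    rates, BI-RADS change tabulation, and diagnosis-time comparison. A
    synthetic lesion phantom generator with independently controllable
    descriptors makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
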