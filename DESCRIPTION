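Package: kneegrade
Title: Automated Kellgren-Lawrence Grading of Knee Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable computer-aided pipeline for
    Kellgren-Lawrence (KL) grading of knee osteoarthritis from bilateral
    knee radiographs. Provides a synthetic phantom-radiograph generator
    with known per-knee KL grades and ground-truth geometry; automated
    knee isolation via sharpening, Otsu thresholding, morphological
    opening and column-projection detection; patient-level leakage-free
    splitting with affine augmentation; a transfer-learning classifier
    architecture with exact per-layer parameter accounting (DenseNet-121
    and related backbones) plus a compact trainable profile with
    hand-verified gradients; one-vs-rest multiclass evaluation metrics;
    and classical machine-learning baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart,
    png,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo:
    Rcpp
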