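Package: radsig
Title: Radiation-Exposure Signatures from ATR-FTIR Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for detecting ionizing-radiation
    exposure from attenuated-total-reflection Fourier-transform infrared
    (ATR-FTIR) hyperspectral images of skin. Provides a seeded synthetic
    focal-plane-array data generator, per-pixel quality control (amide
    signal-to-noise and CO2-contamination filters with noise-ranked capping),
    a five-step spectral pretreatment pipeline (range clipping, dead-pixel
    filling, median denoising, rubber-band baseline correction, amide-II peak
    normalization), embedding-based pixel outlier masking, Savitzky-Golay
    second-derivative biomarker extraction with peak-shift analysis, five
    pixel-level classifier families with sample-level majority-vote
    aggregation, and a stratified evaluation suite (balanced accuracy, ROC,
    specificity at fixed sensitivity, permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    glmnet,
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    yaml,
    withr
Config/testthat/edition: 3
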