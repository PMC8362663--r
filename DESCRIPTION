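Package: nirscgan
Title: Conditional-GAN Data Augmentation for fNIRS Motor-Task Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for ternary motor-task classification
    (right-hand tap, left-hand tap, foot tap) from multichannel fNIRS
    hemodynamic recordings: zero-phase Butterworth band-pass filtering,
    trial epoching and baseline correction, window-mean feature extraction,
    kernel PCA, Gramian Angular Summation Field (GASF) image encoding, a
    class-conditional generative adversarial network for data augmentation,
    a convolutional task classifier, MS-SSIM diversity diagnostics, and an
    augmentation-fraction evaluation sweep. Includes a seeded synthetic
    fNIRS generator emulating task-evoked hemodynamics with hemispheric
    lateralization and physiological noise, so the full pipeline is
    testable without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
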