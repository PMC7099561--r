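Package: fazseg
Title: Automatic Segmentation and Quantification of the Superficial
    Foveal Avascular Zone in OCTA Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for automatic segmentation and physical-area
    quantification of the superficial foveal avascular zone (sFAZ) in en-face
    optical coherence tomography angiography (OCTA) images, robust to the
    brightness/contrast rendering settings of the exporting device. Includes a
    seeded synthetic OCTA cohort simulator (vessel plexus, parametric FAZ,
    nine brightness/contrast renderings per subject), min-max normalisation
    and rigid augmentation, a squeeze-and-excitation encoder-decoder
    segmentation network with a built-in training engine (Adam,
    plateau-halving learning rate, best-on-test checkpointing,
    participant-based stratified cross-validation), binary-mask morphology
    (largest connected region, hole filling), Dice/sensitivity/specificity
    evaluation with threshold sweeps, and per-group reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
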