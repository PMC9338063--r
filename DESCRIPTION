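Package: peflow
Title: Two-Phase Deep Learning Pipeline for Pulmonary Embolism Detection on
    CT Pulmonary Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-phase multitask pipeline for detecting pulmonary
    embolism (PE) and characterizing its attributes from CT pulmonary
    angiography studies. Phase one converts raw CT series to Hounsfield units,
    resamples to 1 mm isotropic spacing, localizes the lungs, splits studies
    into 10-slice 3D windows rendered through three radiological display
    windows, and fine-tunes a 3D convolutional backbone to produce 512-d
    window features. Phase two canonicalizes per-study feature sequences,
    runs a temporal convolutional network with per-label attention pooling,
    and jointly predicts window-level PE presence plus nine study-level
    attributes under a weighted multitask cross-entropy. Includes phantom CT
    and synthetic feature generators, ROC/AUROC evaluation with DeLong
    confidence intervals, threshold selection, feature-space separation
    statistics, attention saliency maps, and 3D Grad-CAM heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
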