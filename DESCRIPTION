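Package: bcrcnn
Title: Two-Stage Breast Tumor Detection and Diagnosis in DCE-MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An improved two-stage region-based detector for benign/malignant
    breast lesion detection and diagnosis on dynamic contrast-enhanced MRI
    slices. Implements background-noise subtraction and short-side rescaling,
    a region proposal network with optional feature pyramid, quantization-free
    ROI alignment, a class-conditional ROI-refinement diagnosis stage with
    extra convolutional feature extractors, the composite five-term training
    loss, lesion-level detection metrics (mAP50, ROC/AUC, sensitivity, false
    positive rate), and dual-plane four-quadrant 3D localization. Ships a
    deterministic dual-plane breast phantom generator with PASCAL VOC2007
    annotations and known quadrant ground truth for end-to-end exercise of the
    pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    xml2,
    yaml,
    png,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
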