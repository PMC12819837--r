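Package: seafec
Title: Dual-Branch Adaptive Receptive-Field and Edge-Enhancement
    Convolution for Agricultural Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements SEAFEC, a plug-and-play convolutional operator for
    plant-disease and weed imagery that fuses a spatial-channel adaptive
    receptive-field attention branch (SCARF, with efficient channel
    attention recalibration) and a multi-scale learnable edge-enhancement
    branch (MEFE) through a sigmoid-gated learnable weight. Provides the
    full forward/backward operator stack on dense rank-4 feature maps,
    backbone surgery for ResNet-18 classification and DeepLabV3-ResNet50
    segmentation networks, deterministic parameter and multiply-accumulate
    accounting, seeded synthetic fixture generators for spot/strip lesion
    classification, crop-weed segmentation and dense lesion detection
    regimes, an augmentation-doubling policy, and metric suites (accuracy,
    macro precision/recall/specificity/F1, mIoU, mAP at IoU thresholds)
    with a desk-scale training harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
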