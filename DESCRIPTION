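Package: adrenalseg
Title: Two-Stage Cascade for Adrenal Incidentaloma Recognition on Nonenhanced CT
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a two-stage cascade for automatic recognition of
    adrenal incidentalomas (AIs) on nonenhanced abdominal CT: a 3-D residual
    U-Net (implemented natively, with Rcpp/Armadillo convolution kernels)
    segments the left and right adrenal glands, and per-gland radiomic
    features feed side-specific binary classifiers.  Ships a synthetic
    CT-phantom generator with paired ground-truth masks and per-side AI
    labels, a minimal NIfTI-1 reader/writer, the standard preprocessing
    chain (PLI reorientation, resampling to fixed spacing, abdominal-window
    normalisation, patch sampling, augmentation), combined Dice + focal
    training loss with sliding-window inference, connected-component
    postprocessing, segmentation metrics (DSC, IOU, RVE, HD95), radiomic
    feature extraction and selection, a panel of classifiers with ROC/AUC,
    Youden-optimal thresholds, confusion-matrix summaries, and the DeLong
    test for paired AUC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    FNN,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
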