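Package: darsunet
Title: Retinal Vessel Segmentation with a Double-Attention Nested U-Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments retinal blood vessels in fundus photographs with a
    nested U-structure of double-attention residual U-blocks (DARSU):
    attention gates on every skip connection, spatial and channel attention
    (CBAM) on block outputs, and a dilated-convolution bottleneck, trained
    with deeply supervised Dice plus cross-entropy loss. Includes the
    standard fundus preprocessing chain (green channel, CLAHE, gamma
    correction), exact flip/translation augmentation bookkeeping, a seeded
    generator of vessel-tree phantoms with pixel-perfect ground truth, and
    the usual segmentation metrics (accuracy, sensitivity, specificity,
    F1, mean IoU). The network runs on a small built-in reverse-mode
    autodiff engine with C++ convolution kernels, so no external
    deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
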