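Package: cattlepose
Title: Lightweight Anchor-Free Cattle Pose Estimation with Parameter-Free
    Attention and Structural Reparameterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for 16-keypoint cattle pose estimation built around a
    lightweight anchor-free convolutional architecture. Provides the SimAM
    parameter-free attention operator, structurally reparameterizable
    multibranch convolution units (RepBlock/RepConv) that fuse into single
    3x3 convolutions for inference, a bidirectional multi-scale fusion neck
    (EfficientRepBiPAN), object-keypoint-similarity (OKS) and average
    precision evaluation with condition-stratified reporting, lossless
    conversion between Labelme-style JSON and YOLO-pose text annotations,
    a procedural generator of synthetic cattle scenes with exact ground
    truth, and a minimal CPU training loop with reverse-mode automatic
    differentiation so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
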