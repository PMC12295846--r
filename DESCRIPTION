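Package: rpanet
Title: Spatiotemporal Endoscopic Video Classification with Residual
    Parallel-Attention 3D Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies variable-length medical (endoscopy-like) videos with
    a 3D convolutional network built from (2+1)D factorized residual blocks
    fused with parallel spatial and channel squeeze-and-excitation attention
    (P-scSE3D).  Provides frame-gap segment sampling for variable-length
    video, a balanced multi-run training and evaluation protocol with paired
    significance testing, Guided Grad-CAM saliency for the 3D model, and a
    seed-reproducible synthetic endoscopy video generator so the full
    pipeline runs without any external dataset.  The network forward and
    backward passes are implemented directly on BLAS matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    png,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
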