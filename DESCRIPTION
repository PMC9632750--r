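Package: lesionfuse
Title: Fusion-Network Pipeline for Pigmented Skin Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dermoscopic image classification under severe class
    imbalance. Implements imbalance-correcting augmentation (mirror-rotation
    upsampling, style-transfer upsampling with exact per-class count
    allocation, class weights, pixel perturbation), three multi-backbone
    fusion architectures with convolutional block attention (CBAM), a
    two-phase freeze/unfreeze transfer-learning trainer, a confusion-matrix
    metric suite with support-weighted aggregation and one-vs-rest AUC, and
    Grad-CAM / Grad-CAM++ saliency maps. A compact layer-graph neural-network
    engine written in base R backs the model components so the whole pipeline
    is testable at desk scale on synthetic lesion images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
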