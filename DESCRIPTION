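Package: bfpcnet
Title: Binocular Fundus Photograph Classification with Residual Attention and Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-label classification of paired (left/right eye) fundus
    photographs across eight ODIR-style disease categories. Implements a
    weighted Gaussian background-subtraction enhancement for retinal images,
    a residual channel-and-spatial attention block embedded in a residual
    convolutional backbone, a two-branch binocular feature-fusion head, and
    a label-smoothed cross-entropy loss, together with manifest handling,
    stratified 4/1 train/test splitting, augmentation-driven class
    balancing, per-class confusion metrics, and a deterministic synthetic
    paired-image generator for fully offline testing. The network and its
    training loop (Adam, backpropagation) are implemented in base R on
    BLAS-backed matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
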