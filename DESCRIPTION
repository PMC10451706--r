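Package: dduda
Title: Boundary-Enhanced Dual-Discriminator Domain Adaptation for 2D CT Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Adversarial unsupervised domain adaptation for 2D liver
    segmentation from CT slices. Implements a boundary-enhanced
    encoder-decoder segmentation network (one encoder, a segmentation
    decoder and an auxiliary boundary decoder trained against Sobel edge
    labels) together with two fully convolutional domain discriminators,
    one at the feature level and one at the output level. Provides CT
    windowing and normalization, the dice, boundary, adversarial and
    classification losses, the five-step alternating training procedure,
    overlap metrics (dice, IoU, sensitivity, precision), and a seeded
    two-domain phantom generator so the whole pipeline can be exercised
    without clinical data. The convolutional network machinery is
    implemented in compiled code on the system BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
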