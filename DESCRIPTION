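Package: tasselsynth
Title: Adversarial Synthesis of Field-Style Maize Tassel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates labelled field-style images of maize tassels against
    sky backgrounds by training two separate deep convolutional generative
    adversarial networks (a residual-deconvolution tassel generator without
    batch normalization, and a sky-patch generator) and compositing their
    outputs with a luminance-corrected Otsu mask, weighted edge blending and
    bicubic rescaling. Includes dataset preparation (center cropping, YCbCr
    chroma segmentation, saturation/luminance augmentation, dark-sky
    filtering), procedural fixture generators for fully self-contained
    testing, and an evaluation suite: structural similarity (SSIM) pairing
    protocols, bounding-box morphometrics, a k-nearest-neighbour data
    augmentation experiment, perceptual-test deck construction with
    confusion summaries, and a lower bound on inter-annotator error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
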