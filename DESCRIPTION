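Package: nrem
Title: Nonreference Reconstruction-Based Edge Map Quality Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: No-reference quality assessment of binary edge maps for
    grayscale (notably medical) images. An edge map is scored by dilating
    it, retaining the original intensities on the dilated mask, predicting
    every remaining pixel from the nearest edge intensities along the eight
    compass directions (weighted mean, weighted median, central weighted
    median, or alpha-trimmed weighted mean interpolation), comparing the
    reconstruction to the original with a gradient-based structural
    similarity index, and penalizing edge-pixel density. The resulting
    score ranks edge detectors and selects detector thresholds without any
    ground-truth reference. A consensus ROC baseline (potential ground
    truths, correspondence-threshold ROC, best-map selection), built-in
    gradient edge detectors, and a synthetic phantom generator with exact
    ground-truth edges are included, along with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
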