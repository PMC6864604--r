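Package: lfaquant
Title: Smartphone-Based Quantification of Lateral Flow Assay Strips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads photographs of lateral flow assay (LFA) strips framed in a
    3x3 camera grid, extracts the control- and test-line regions from the
    center grid cell, segments the reddish bands with an Otsu threshold on the
    red/green channel-ratio image, and quantifies band signal as the weighted
    sum of red intensities. The test-to-control (T/C) ratio is calibrated
    against log10 analyte quantity by ordinary least squares, yielding
    standard error of detection, R-squared, limits of detection and
    quantification, and per-class coefficients of variation. Unknown strips
    are classified into quantity classes with a one-vs-one linear support
    vector machine on the calibrated quantities, with stratified k-fold cross
    validation and confusion-matrix reporting. A seeded synthetic strip-image
    generator with known ground truth makes the whole pipeline testable
    without photographs, and a command-line interface exposes simulation,
    analysis, calibration, classification and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
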