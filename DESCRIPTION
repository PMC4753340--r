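Package: dcfseg
Title: Automatic Extraction and Thickness Measurement of the Deep
    Cervical Flexor from Cervical Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automatic computer-vision pipeline that segments the
    Deep Cervical Flexor (DCF) muscle band in B-mode cervical ultrasound
    and measures its thickness at three calibrated points anchored on the
    leftmost cervical vertebra.  Implements ends-in search contrast
    stretching, average/Otsu/fuzzy-sigma binarization, connected-component
    noise filtering with size and location criteria, boundary hole
    filling, 4-directional contour tracing, natural cubic-spline boundary
    reconnection, DDA line rasterization, distance-weighted intensity
    restoration and anatomical key-point localization.  Ships a synthetic
    craniocervical sonogram phantom generator with full ground truth so
    the whole pipeline is testable without clinical data, DICOM/PNG/TIFF
    input with physical pixel-spacing calibration, and a command-line
    interface for single-image and batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
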