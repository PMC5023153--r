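Package: filmdose
Title: Radiochromic Film Dosimetry with a Generic Calibration Curve and
    One-Scan Rescaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end radiochromic film dosimetry for patient-specific
    IMRT/VMAT quality assurance. Fits rational per-channel dose-response
    calibration curves, adapts a generic (lot-level) calibration to any
    scanner and scan session via the One-scan two-reference-film affine
    rescaling, reconstructs absolute dose maps by triple-channel analysis
    with a per-pixel multiplicative disturbance correction, and validates
    them against a planned dose grid with a gamma-index (3%/3 mm) test.
    Includes a flatbed-scanner and film simulator so every stage of the
    workflow can be exercised and verified without physical film.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
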