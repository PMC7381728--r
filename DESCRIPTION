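Package: sonoperf
Title: Quantitative Contrast-Enhanced Ultrasound Perfusion Analysis for
    Sonopermeation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative contrast-enhanced ultrasound (qCEUS)
    perfusion monitoring during microbubble-mediated sonopermeation therapy.
    Extracts region-of-interest time-intensity curves from contrast-mode
    image sequences, detects flash-destruction pulses, fits the exponential
    destruction-replenishment model y = A(1 - exp(-beta*t)) to recover
    relative blood volume (RBV = A) and reperfusion rate (RR = beta),
    reconstructs tumor volume and contrast-derived blood volume from stepped
    2D sweeps, and performs paired treated-versus-control pre/post treatment
    inference with control-normalized percent changes. Includes a synthetic
    CEUS phantom generator with known ground truth for validation, plus
    readers and writers for multi-page TIFF sequences with JSON sidecars,
    label masks, YAML protocol configurations, and CSV/JSON result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
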