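Package: calcytox
Title: Simulation and Image-Cytometry Analysis of Calcein-Release
    Cytotoxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the 4-hour calcein-AM natural killer (NK) cell
    cytotoxicity assay, covering both the classical supernatant-release
    readout and the image-cytometry live-cell-count readout. Provides a
    mechanistic, seeded simulator of calcein loading, spontaneous leak and
    NK-mediated lysis (necrosis-like release versus apoptotic-body
    retention), a synthetic fluorescence-image renderer with a
    Poisson-Gaussian camera model, object detection with integrated-intensity
    gating against spontaneous controls, both percent-specific-lysis
    formulas, and an exact Wilcoxon matched-pairs signed-rank comparison
    between methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
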