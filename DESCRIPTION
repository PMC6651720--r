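Package: pnlmg
Title: Speckle-Noise Suppression and Gray-Value Restoration for
    Porous-Silicon Microarray Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for restoring the average gray level of laser-speckle
    corrupted images of porous-silicon (PSi) microcavity microarrays, where
    the mean gray value of each array unit is the biosensing signal.
    Implements probability-based non-local means filtering (PNLM) driven by
    the rank-ordered absolute differences (ROAD) impulse statistic, followed
    by gradient-magnitude marking of residual singular pixels and selective
    median repair (the PNLM-G pipeline).  Also provides a multiplicative
    speckle simulator with analytic intensity densities, restoration metrics
    (average gray level, speckle index, PSNR, ENL), Lee and adaptive-median
    baseline filters, synthetic microarray generation and per-unit gray-level
    quantification, linear gray/refractive-index calibration fits, and a
    scripted Monte-Carlo harness for ensemble experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
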