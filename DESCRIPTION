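Package: sfpdiam
Title: Single Muscle Fiber Potential Simulation and Fiber Diameter Estimation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Line-source volume-conductor simulation of extracellular single
    muscle fiber action potentials (SFPs) and estimation of muscle fiber
    diameter and fiber-to-electrode distance from two waveform features:
    peak-to-peak amplitude and negative-peak duration.  Provides the forward
    simulator (propagating transmembrane current convolved with an
    anisotropic weight function), feature extraction with interpolated
    zero-crossings, bi-quadratic feature surfaces with a published
    coefficient set and a least-squares refit engine, closed-form quadratic
    solvers with measurement-error sensitivity analysis, and a nomogram of
    iso-amplitude and iso-duration curves in the diameter-distance plane.
    Includes a command-line interface for batch simulation and inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
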