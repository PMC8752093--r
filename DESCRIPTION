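Package: fcspipe
Title: Two-Color Fluorescence Correlation Spectroscopy Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of two-color fluorescence correlation
    spectroscopy (FCS) measurements: auto- and cross-correlation of binned
    photon-count traces on a multi-tau lag grid, photobleaching detrending,
    uncorrelated-background correction, fitting of the single-component
    three-dimensional Gaussian free-diffusion model, reference-dye calibration
    of diffusion coefficients and molar concentrations, Stokes-Einstein
    complex-size inference, and rank-based ensemble statistics over per-cell
    measurements. Includes a Brownian-dynamics generator of synthetic
    two-channel photon-count traces with known ground truth so that every
    stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
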