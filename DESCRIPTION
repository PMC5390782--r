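Package: sptfcs
Title: Convergent Analysis of Membrane Diffusion by Single-Particle
    Tracking and STED-FCS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for reconciling lateral membrane-diffusion measurements
    from camera-based single-particle tracking (SPT) and (STED-)fluorescence
    correlation spectroscopy (FCS). Simulates compartmentalized
    two-dimensional diffusion (free, confined, hop, immobile) degraded by a
    realistic camera model (finite-exposure motion blur and Gaussian
    localization noise), computes ensemble mean-squared-displacement curves
    with per-lag dispersion, fits blur- and noise-corrected apparent
    diffusion models (free, anomalous, confined, corral, mixed, and hop
    diffusion) by weighted nonlinear least squares with AIC/BIC model
    selection, simulates and analyzes FCS intensity traces with a
    multiple-tau correlator and spot-size calibration, and superimposes
    both modalities in a common apparent-diffusion-coefficient-versus-time
    representation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
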