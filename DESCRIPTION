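Package: virtangio
Title: Patient-Individualized Virtual Digital Subtraction Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for virtual digital
    subtraction angiography (DSA). Contrast agent is transported through a
    level-set vessel geometry as massless particles driven by a time-varying
    velocity field (fourth-order Runge-Kutta advection, wall bounce-back,
    Gaussian particle-to-concentration smoothing, boundary extension by
    distance transform, and gradient-drift diffusion). Patient-specific
    parameters (heart rate, heart-state phase, capacitor-model bolus
    injection profile) are extracted from 2D DSA sequences via
    time-intensity curves; concentration volumes are forward-projected with
    C-arm cone-beam projection matrices and ray casting; and real and
    virtual angiograms are compared with time-intensity-curve metrics
    (FWHM, time-to-peak, average wash-in/wash-out, shift/scale-aligned
    relative RMSE). Includes analytic phantom geometries, pulsatile inflow
    waveforms, and a synthetic DSA generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
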