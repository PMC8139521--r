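Package: sptEM
Title: Joint Localization and Diffusion Estimation for Single Particle
    Tracking by Expectation-Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simultaneous localization and diffusion-coefficient estimation
    from segmented fluorescence image sequences of a single diffusing
    emitter. Implements a forward camera model (Gaussian point spread
    function integrated over pixels, Poisson shot noise, uniform background,
    and optional pixel-dependent sCMOS readout noise), the standard two-step
    baselines (Gaussian fitting followed by mean-square-displacement or
    Kalman-likelihood estimation, and an sCMOS-aware maximum-likelihood
    localizer), and an expectation-maximization framework whose E-step is
    computed either by an unscented Kalman filter with unscented
    Rauch-Tung-Striebel smoothing on variance-stabilized counts (U-EM) or by
    a bootstrap particle filter with forward-filter backward-smoothing on
    the raw pixel likelihood (SMC-EM). A benchmarking harness reproduces
    success maps, localization error curves, and diffusion-threshold scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
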