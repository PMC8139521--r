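# sptEM

Joint localization and diffusion-coefficient estimation for single particle
tracking (SPT) from segmented fluorescence camera images.

## The problem

SPT experiments follow one fluorescently labelled molecule through a
time-lapse image sequence. After segmentation, the data for one particle are
N small P × P pixel frames; the scientific quantity of interest is usually
the diffusion coefficient. The standard two-step pipeline localizes the
emitter frame by frame (Gaussian fitting of the point spread function),
links the localizations into a trajectory, and then estimates the diffusion
coefficient from that trajectory with mean-square-displacement (MSD) fitting
or a Gaussian state-space maximum-likelihood estimator (MLE). But
localization and motion estimation are coupled, and at low photon counts the
two-step approach degrades badly.

`sptEM` implements the joint alternative: the particle positions
X_t are the hidden states of a state-space model

    X_{t+1} = X_t + W_t,            W_t ~ N(0, diag(2 Dx dt, 2 Dy dt))
    I_{p,t} ~ Poisson(lambda_p(X_t) + N_bgd) (+ sCMOS readout noise)

where lambda_p is the Gaussian PSF integrated over pixel p, and an
expectation–maximization (EM) loop estimates (Dx, Dy) directly from the
pixel counts. The E-step (the smoothed posterior of the trajectory, with
lag-one covariances) comes from one of two backends:

* **U-EM** — Anscombe variance-stabilizing transform of the counts, an
  unscented Kalman filter, and an unscented Rauch–Tung–Striebel smoother.
  Fast (cost linear in pixels per frame), limited to small 2 D dt.
* **SMC-EM** — a bootstrap particle filter on the exact pixel likelihood and
  a forward-filter backward-smoother (FFBS). Handles arbitrary posteriors;
  cost quadratic in the particle count.

The M-step maximizing the expected complete-data likelihood over (Dx, Dy) is
closed form. The package also contains the full forward simulator (pixel
integration, shot noise, motion blur over the shutter, per-pixel sCMOS gain
and read-noise maps, per-frame re-centred segmentation windows), the
baselines (GF-MSD, GF-MLE, and an sCMOS-aware ML localizer), and a
benchmarking harness (localization RMSE, success maps over signal and
background, diffusion-threshold scans against the Rayleigh criterion
0.61 λ / NA). See the methods vignette (`vignettes/spt-em-methods.Rmd`) for
the model details and design choices.

## A worked example

```r
library(sptEM)
cfg <- sceneConfig()        # 25 x 25 px, 100 frames at 10 Hz, 10 ms shutter,
                            # G = 100, Nbgd = 10, Dx = 0.005, Dy = 0.01 um^2/s
set.seed(7)
trj <- simulateTrajectory(cfg)
stk <- renderStack(trj, cfg)

# standard two-step pipeline
loc <- localizeStack(stk, "gf")
mleDiffusion(as.matrix(loc[, c("x", "y")]), cfg@dt)$D
#> [1] 0.00391 0.01270

# joint estimation
set.seed(8)
em <- runEM(stk, uEmBackend())
em
#> EMResult [u-em]: 8 iterations
#>   final Dx = 0.004064, Dy = 0.01163 um^2/s
rmse(smoothedMean(posteriorOf(em)), truePositions(stk))
#>    x    y
#> 6.54 6.04
```

Both pipelines recover the diffusion coefficients (truth 0.005 and 0.01
µm²/s) within single-trajectory sampling error; the EM smoothed means track
the particle to ~6.5 nm per axis, far below the 274.5 nm diffraction limit.
Replace `uEmBackend()` with `smcEmBackend(500)` for the particle-based
E-step, or use `runExperiment()` / `thresholdScan()` / `successMap()` to
reproduce whole benchmark grids. A small command-line wrapper is installed
at `inst/cli/sptem.R` (`simulate`, `analyze`, `benchmark`, `maps`
subcommands).

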