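---
title: "Joint localization and diffusion estimation for single particle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint localization and diffusion estimation for single particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptEM)
```

# The problem

Single particle tracking (SPT) follows one fluorescently labelled molecule
through a time-lapse fluorescence image sequence and asks how it moves — here,
what its diffusion coefficients $D_x, D_y$ are. The data are *segmented*
camera frames: small $P \times P$ pixel windows, each containing (an image of)
one emitter. The standard two-step pipeline localizes the emitter in every
frame, links the localizations into a trajectory, and then fits a motion model
to that trajectory. Localization and motion estimation are coupled, however:
how well you can pin down the particle depends on how it moves, and the motion
parameters are estimated from the noisy localizations. `sptEM` implements a
family of expectation–maximization (EM) estimators that treat the particle
positions as the *hidden states* of a state-space model and estimate the
diffusion coefficients directly from the pixel data, alongside the standard
two-step baselines and a camera simulator that generates all test data.

# The forward model

**Motion.** Free Brownian diffusion sampled at the frame interval
$\Delta t$:
$$X_{t+1} = X_t + W_t, \qquad W_t \sim N(0, Q), \quad
  Q = \mathrm{diag}(2 D_x \Delta t,\; 2 D_y \Delta t).$$
The simulator generates the motion on a finer grid of $N_{sub}$ sub-steps per
frame so that motion during the shutter time can be represented.

**Optics.** A sub-diffraction emitter images as the point spread function,
approximated by a 2-D Gaussian of width
$\sigma = \sqrt{2}\,\lambda / (2 \pi \mathrm{NA})$ (101.3 nm for the default
540 nm emission and NA 1.2). The expected *signal* photons in a pixel are the
PSF integrated over the pixel box, a separable product of error-function
differences (`expectedPixelRates()`), with peak rate $G$ photons/frame.

**Camera.** Each pixel adds a uniform background rate $N_{bgd}$ and draws a
Poisson count (shot noise). The *ideal* camera stops there. The *sCMOS*
camera multiplies the photon count by a per-pixel gain $g_p$ and adds
zero-mean Gaussian read noise with per-pixel variance $\sigma^2_p$; the exact
measurement density is the Poisson–Gaussian convolution
(`scmosPixelDensity()`), evaluated with a truncated sum whose window is
centred on the summand's mode (neglected mass below $10^{-12}$).

**Motion blur.** The camera accumulates photons for a shutter time $\delta t$
(10 ms of the 100 ms frame interval by default). A frame is rendered from the
*mean rate map* over the sub-positions spanned by the shutter and a single
Poisson draw per pixel; averaging independently drawn sub-frames is available
(`averageSubFrames`) but off by default, since the accumulated photon count
of a shutter period is a single Poisson observation of the integrated rate.

**Ground truth for scoring.** A blurred frame does not encode the
frame-start position; it encodes the shutter-averaged position. The
per-frame ground truth stored in a `FrameStack` is therefore the mean
sub-position over the shutter window, which is also what localization error
is measured against. (With `nSub = 1` there is no blur and this equals the
frame-start state.)

**Segmentation.** Real pipelines cut a window around the detected particle in
every frame, so the emitter is always near the window centre no matter how
far it diffuses. The simulator reproduces this with
`segmentation = "tracked"` (default): each frame's window is centred on the
frame-start position, snapped to the pixel grid, and the per-frame window
origins are carried in the `FrameStack` (they are segmentation output, so
the estimators may use them). Without re-centring (`"fixed"`), a particle
with $D \gtrsim 0.5\ \mu m^2/s$ leaves the default 2.5 µm field within the
10 s sequence and every estimator fails for the trivial reason that the data
no longer contain the particle. For the sCMOS camera the calibration maps
are treated as attached to the window (constant in window coordinates); at
the low diffusion coefficients where the sCMOS comparisons run, the window
moves by at most a pixel or two, so the approximation is mild.

# Estimators

## Two-step baselines

*Gaussian fitting (GF)* fits the pixel-sampled Gaussian-plus-background model
to each frame by least squares, with $(x_o, y_o, G)$ free and the PSF width
fixed at its optical value. Starting points come from the top peaks of a
PSF-matched-filtered frame (multi-start); position estimates are clipped to
the segmented window. *MSD* fitting computes the mean square displacement
curve and fits $\mathrm{MSD}(n) = 2 D n \Delta t$ through the origin over all
lags (linear in $D$, so the optimum is the closed-form regression slope;
common practice fits few lags, but all lags are used here and `maxLag` is
exposed for sensitivity analysis). The *MLE* baseline treats the localized
positions as direct observations of a random walk with additive Gaussian
noise of variance $R$ and maximizes the exact Gaussian state-space
likelihood over $(D, R)$ — evaluated by a Kalman recursion with a diffuse
initial state, which makes the likelihood translation invariant — via
bounded quasi-Newton from multiple starts. No motion-blur correction term is
applied to the observation variance.

*sCMOS localization* (for pixel-dependent read noise) uses the
noise-augmented Poisson approximation: gain-corrected counts
$I_p/g_p + \sigma_p^2/g_p^2$ are modelled as Poisson with rate
$\lambda_p + N_{bgd} + \sigma_p^2/g_p^2$ and the likelihood maximized over
$(x_o, y_o, G)$. At signal-to-background ratio near one, the *global* pixel
likelihood develops spurious optima at transient background fluctuations far
from the emitter; the fit is therefore confined to a box around the detected
spot, and `localizeStack()` applies the linking step of the standard
pipeline: per-frame best-likelihood fits over the top candidates, then a
second pass that refits any frame lying more than a gate radius (4 pixels by
default) from the 5-frame temporal-median track anchor. Background
detections are isolated in time, so the running median is a robust anchor.

## The EM framework

The frames are observations $Y_t$ of the hidden positions $X_t$. EM
alternates an E-step — computing the smoothed posterior
$p(X_t \mid Y_{1:N})$ and the pairwise $p(X_t, X_{t-1} \mid Y_{1:N})$ under
the current $\theta^{(e)} = (D_x, D_y)$ — with a closed-form M-step,
$$\hat D_a = \frac{1}{2 n \Delta t} \sum_t \left[(m_{t,a} - m_{t-1,a})^2 +
  P_{t,aa} + P_{t-1,aa} - 2 C_{t,t-1,aa}\right],$$
where $m, P, C$ are the smoothed means, variances and lag-one covariances.
Only $(D_x, D_y)$ are estimated; $G$ and $N_{bgd}$ are assumed known, and
the initial-state prior — a Gaussian centred on the first-frame localization
with 100 nm (one pixel) per-axis standard deviation — is held fixed rather
than re-estimated. $\theta^{(0)}$ defaults to the GF + MSD estimate on the
same frames (fast and always available). The loop runs at most 10 iterations
(diffusion-coefficient traces flatten after a handful) with early stopping
at a relative parameter change below $10^{-4}$.

Two E-step backends implement the smoothing:

**U-EM** first stabilizes the variance of the counts with the Anscombe
transform $\tilde I = 2\sqrt{I + 3/8 + \sigma^2_p/g_p^2}$, after which each
pixel is approximately Gaussian with unit variance around
$2\sqrt{\lambda_p(X_t) + N_{bgd} + 3/8 + \sigma^2_p/g_p^2}$. (The background
rate belongs inside the square root: the transform is applied to raw counts
that include background, so the model must include it too.) An unscented
Kalman filter handles the nonlinear measurement function through sigma
points — spread parameters $\alpha = 1$, $\beta = 2$, $\kappa = 1$, exposed
in `ukfSettings()` — and an unscented Rauch–Tung–Striebel smoother runs the
backward pass; with linear dynamics the smoother gain is
$G_t = P_{t|t} P_{t+1|t}^{-1}$ and the lag-one covariances follow
$C_{t+1,t|N} = P_{t+1|N} G_t^\top$. The innovation covariance is unit-diagonal
plus a rank-4 term, inverted with the matrix-inversion lemma, so the filter
is linear in the number of pixels. Numerical hygiene: covariances are
symmetrized with a $10^{-12}$ nm² diagonal jitter before Cholesky
factorization; a failed factorization or loss of positive definiteness sets
the failure flag — this, and severe nonlinearity across widely spread sigma
points, is how the backend degrades at large $2 D \Delta t$.

**SMC-EM** is a bootstrap particle filter on the *raw* pixel likelihood
(Poisson for the ideal camera, Poisson–Gaussian for sCMOS): particles are
propagated by the diffusion prior, reweighted in the log domain
(log-sum-exp normalization), and systematically resampled when the effective
sample size drops below half the particle count. Smoothing uses
forward-filter backward-smoothing (FFBS) reweighting, which costs
$O(N_p^2)$ per frame but directly yields the pairwise expectations
$E[X_t X_{t-1}^\top \mid Y]$ the M-step needs — the reason it is preferred
here over backward simulation. Pixels far (beyond eight PSF widths) from
every particle contribute a position-independent factor that cancels in the
normalized weights and is computed once per frame.

# What the simulator does and does not emulate

The generator reproduces: pixel-integrated Gaussian optics, shot noise,
uniform local background, motion blur by rate smearing, per-pixel sCMOS gain
and read noise (log-normal variance, median 2.0 counts² with log-sd 0.6, and
Gaussian gain, mean 2.0 sd 0.1 truncated at 0.5 — synthetic placeholders
with no calibration provenance, configurable in `makeScmosMaps()`), and
per-frame re-centred segmentation windows. It does not emulate: non-Gaussian
or defocused PSFs, emitter photophysics (blinking, bleaching), multiple
emitters per window, segmentation errors (windows are centred on the true
position), sample drift, or spatially structured background. Passing tests
therefore validate the estimators under the stated model, not robustness to
these real-data effects.

# Numerical choices and degenerate inputs

* Rates and likelihoods treat positions in nm; diffusion coefficients are
  µm²/s at the interface (1 µm² = 10⁶ nm²).
* A pure-background frame is unidentifiable for GF: the fit returns
  `converged = FALSE` when the amplitude does not exceed three times the
  background shot scale.
* `mleDiffusion()` returns zero estimates and a degeneracy flag for an
  all-constant track; the M-step clamps $\hat D$ at a tiny positive floor.
* The EM loop aborts with `failed = TRUE` (partial trace retained) if a
  backend diverges; benchmark harness code counts failed runs as infinite
  localization error.
* Threshold scans stop at the first grid point whose aggregate RMSE exceeds
  the Rayleigh limit $0.61 \lambda / \mathrm{NA}$ (274.5 nm for the default
  optics; 270 nm when rounded as commonly printed) — scanning further cannot
  change the reported threshold. The aggregate is the per-grid-point
  *median* of per-sequence RMSEs: near failure the error distribution mixes
  well-tracked runs with rare, recoverable track-loss excursions orders of
  magnitude larger, so a mean over ten sequences is dominated by one or two
  excursions while the median captures the typical tracking quality; summary
  plots in this literature conventionally report medians. The mean is
  computed alongside and available via `aggregate = "mean"`.
* All randomness flows through R's RNG; dataset generation derives one
  substream per sequence (`seed + i`), and analysis uses separate
  substreams, so experiments are pure functions of `(config, seed)` and
  changing the particle count does not perturb the data.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run the reference condition at
$K = 100$ sequences for the frame-wise baselines, $K = 20$–$25$ for the EM
schemes, and $K = 10$ per grid point for the diffusion scans on
$\{0.01, 0.05, 0.1, 0.5, 1, 3, 6, 10\}$ µm²/s; Monte Carlo checks of the
particle smoother use 2000–5000 particles on short linear-Gaussian
sequences. These sizes keep every summary statistic within a couple of
standard errors of its large-$K$ value.

# Known limitations

* The U-EM backend with the default sigma-point spread tolerates somewhat
  larger process noise before breaking down than hand-tuned unscented
  filters are typically reported to; its failure threshold can land one
  logarithmic grid step above published values.
* Robust linking makes Gaussian fitting degrade only gradually under motion
  blur at the default shutter (10% duty cycle): the smeared streak's
  centroid is still recovered, so the blur-condition failure threshold can
  exceed that of a fragile single-start fit.
* FFBS costs $O(N_p^2 N)$; particle counts much beyond a few thousand are
  better served by backward simulation, which is out of scope here.
* The sCMOS gain enters as a known multiplicative map; gain estimation and
  time-varying read noise are not implemented.

# A worked example

```{r example, eval = FALSE}
cfg <- sceneConfig()            # reference condition
set.seed(7)
trj <- simulateTrajectory(cfg)
stk <- renderStack(trj, cfg)

# two-step baseline
loc <- localizeStack(stk, "gf")
mleDiffusion(as.matrix(loc[, c("x", "y")]), cfg@dt)$D

# joint estimation
em <- runEM(stk, uEmBackend())
finalTheta(em)
rmse(smoothedMean(posteriorOf(em)), truePositions(stk))
```
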