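#' Gaussian PSF width from the optics
#'
#' In-focus widefield PSF width for emission wavelength `wavelength` (nm) and
#' numerical aperture `na`:
#' \eqn{\sigma_x = \sigma_y = \sqrt{2}\,\lambda / (2\pi\,\mathrm{NA})}.
#'
#' @param wavelength emission wavelength (nm), positive
#' @param na numerical aperture, positive
#' @return named numeric of length 2, `sigmaX` and `sigmaY` in nm
#' @examples
#' psfSigmaFromOptics(540, 1.2)  # ~101.3 nm
#' @export
psfSigmaFromOptics <- function(wavelength, na) {
  if (!is.numeric(wavelength) || !is.numeric(na) || wavelength <= 0 || na <= 0)
    stop("'wavelength' and 'na' must be positive")
  s <- sqrt(2) * wavelength / (2 * pi * na)
  c(sigmaX = s, sigmaY = s)
}

## number of fine sub-steps the shutter spans
nBlurSteps <- function(config) {
  if (config@nSub == 1L) return(1L)
  as.integer(round(config@shutter / (config@dt / config@nSub)))
}

## per-substep increment variance in nm^2 (D in um^2/s, times in s)
stepVarNm2 <- function(D, dtSub) 2 * D * 1e6 * dtSub

#' Simulate a diffusing ground-truth trajectory
#'
#' Pure Brownian motion: positions on the fine grid of `nSub` sub-steps per
#' frame evolve as \eqn{X_{k+1} = X_k + W_k} with independent zero-mean
#' Gaussian increments of per-axis variance \eqn{2 D \Delta t / N_{sub}}.
#' Draws from the current R RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param config a [SceneConfig-class]
#' @return a [Trajectory-class] with `nFrames * nSub` fine-grid positions and
#'   the frame-start positions (the `nSub`-strided subsequence)
#' @export
simulateTrajectory <- function(config) {
  validObject(config)
  N <- config@nFrames
  M <- N * config@nSub
  dtSub <- config@dt / config@nSub
  sdx <- sqrt(stepVarNm2(config@Dx, dtSub))
  sdy <- sqrt(stepVarNm2(config@Dy, dtSub))
  incx <- if (sdx > 0) rnorm(M - 1, 0, sdx) else numeric(M - 1)
  incy <- if (sdy > 0) rnorm(M - 1, 0, sdy) else numeric(M - 1)
  sub <- cbind(config@initialPosition[1] + c(0, cumsum(incx)),
               config@initialPosition[2] + c(0, cumsum(incy)))
  idx <- (seq_len(N) - 1L) * config@nSub + 1L
  new("Trajectory",
      frameTimes = (seq_len(N) - 1) * config@dt,
      framePositions = sub[idx, , drop = FALSE],
      subPositions = sub)
}

#' Expected signal photons per pixel for one emitter position
#'
#' Integrates the Gaussian PSF over each pixel box: the expected signal in
#' pixel (i, j) is the separable product of error-function differences,
#' \deqn{\lambda_{ij} = G\,2\pi\sigma_x\sigma_y/(\Delta x \Delta y)\,
#'  [\Phi(\frac{b_x - x_o}{\sigma_x}) - \Phi(\frac{a_x - x_o}{\sigma_x})]
#'  [\Phi(\frac{b_y - y_o}{\sigma_y}) - \Phi(\frac{a_y - y_o}{\sigma_y})]}
#' with (a, b) the pixel bounds. Background is not included.
#'
#' @param position length-2 numeric (nm); may lie outside the field
#' @param config a [SceneConfig-class]
#' @return P x P matrix of nonnegative expected signal photons (rows = y)
#' @export
expectedPixelRates <- function(position, config) {
  validObject(config)
  if (length(position) != 2 || any(!is.finite(position)))
    stop("'position' must be a finite length-2 vector (nm)")
  v <- rateMapBatchCpp(position[1], position[2], config@G,
                       config@psfSigmaX, config@psfSigmaY,
                       config@P, config@dx, config@dy)
  matrix(v, config@P, config@P)
}

#' Shutter-averaged expected pixel rates
#'
#' Arithmetic mean of [expectedPixelRates()] over the sub-positions occupied
#' during the shutter period, modelling motion blur as a smeared rate map.
#'
#' @param subPositionsInFrame n x 2 matrix of positions (nm) during the shutter
#' @param config a [SceneConfig-class]
#' @return P x P matrix of expected signal photons
#' @export
blurredRates <- function(subPositionsInFrame, config) {
  sp <- rbind(subPositionsInFrame)
  if (nrow(sp) < 1) stop("at least one sub-position is required")
  v <- rateMapBatchCpp(sp[, 1], sp[, 2], config@G,
                       config@psfSigmaX, config@psfSigmaY,
                       config@P, config@dx, config@dy)
  matrix(rowMeans(v), config@P, config@P)
}

#' Render one camera frame from a rate map
#'
#' Ideal camera: each pixel is a single Poisson draw with mean
#' \eqn{\lambda_p + N_{bgd}}. sCMOS camera: \eqn{g_p \cdot
#' \mathrm{Poiss}(\lambda_p + N_{bgd}) + \epsilon_p} with
#' \eqn{\epsilon_p \sim N(0, \sigma^2_p)} from the calibration maps.
#'
#' @param rates P x P matrix of expected signal photons (background excluded)
#' @param config a [SceneConfig-class]
#' @param maps [CameraMaps-class], required when `cameraKind == "scmos"`
#' @return P x P numeric matrix of measured counts
#' @export
renderFrame <- function(rates, config, maps = NULL) {
  mu <- rates + config@Nbgd
  n <- length(mu)
  shot <- matrix(rpois(n, as.vector(mu)), nrow(mu), ncol(mu))
  if (config@cameraKind == "ideal") return(shot)
  if (is.null(maps))
    stop("camera maps are required for the sCMOS camera model")
  g <- gainMap(maps)
  rv <- readoutVariance(maps)
  g * shot + matrix(rnorm(n, 0, sqrt(as.vector(rv))), nrow(mu), ncol(mu))
}

#' Poisson-Gaussian measurement density of an sCMOS pixel
#'
#' Density of a measured count \eqn{I = g q + \epsilon} where
#' \eqn{q \sim \mathrm{Poiss}(\lambda + N_{bgd})} and
#' \eqn{\epsilon \sim N(0, \sigma^2)}:
#' \deqn{p(I) = \sum_q \frac{e^{-\mu}\mu^q}{q!}
#'   \frac{1}{\sqrt{2\pi\sigma^2}} e^{-(I - g q)^2 / (2\sigma^2)}.}
#' The infinite sum is truncated at
#' \eqn{q \in [\max(0, \lfloor\mu - 10\sqrt{\mu}\rfloor),
#' \lceil\mu + 10\sqrt{\mu} + 10\rceil]}, leaving under 1e-12 of the mass.
#'
#' @param count measured value(s), real
#' @param signalRate expected signal photons \eqn{\lambda \ge 0}
#' @param background expected background photons \eqn{N_{bgd} \ge 0}
#' @param readoutVar readout-noise variance \eqn{\sigma^2 > 0} (counts^2)
#' @param gain pixel gain (counts/photon), default 1
#' @return density value(s), same length as `count`
#' @export
scmosPixelDensity <- function(count, signalRate, background, readoutVar,
                              gain = 1) {
  if (readoutVar <= 0)
    stop("'readoutVar' must be positive; use the Poisson pmf for zero readout noise")
  if (signalRate < 0 || background < 0) stop("rates must be nonnegative")
  mu <- signalRate + background
  if (mu == 0) return(dnorm(count, 0, sqrt(readoutVar)))
  scmosPdfCpp(as.numeric(count), mu, gain, readoutVar)
}

#' Generate synthetic sCMOS calibration maps
#'
#' Per-pixel readout variance is drawn log-normally and per-pixel gain
#' normally (truncated below). The default parameters are synthetic
#' placeholders chosen to resemble a back-illuminated sCMOS sensor; they are
#' configurable and carry no calibration provenance.
#'
#' @param P pixels per side
#' @param varMedian median readout variance (counts^2), default 2.0
#' @param varLogSd log-scale standard deviation of the variance, default 0.6
#' @param gainMean mean gain (counts/photon), default 2.0
#' @param gainSd gain standard deviation, default 0.1
#' @param gainFloor lower truncation for the gain, default 0.5
#' @return a [CameraMaps-class]; draws from the current R RNG stream
#' @export
makeScmosMaps <- function(P, varMedian = 2.0, varLogSd = 0.6, gainMean = 2.0,
                          gainSd = 0.1, gainFloor = 0.5) {
  if (varMedian <= 0 || varLogSd < 0 || gainMean <= 0 || gainSd < 0 ||
      gainFloor <= 0)
    stop("distribution parameters must be positive")
  rv <- matrix(exp(rnorm(P * P, log(varMedian), varLogSd)), P, P)
  g <- matrix(rnorm(P * P, gainMean, gainSd), P, P)
  g <- pmax(g, gainFloor)
  cameraMaps(rv, g)
}

#' Render a full frame stack from a trajectory
#'
#' Each frame uses the mean rate map over the sub-positions spanned by the
#' shutter (motion blur as rate smearing, a single Poisson draw per pixel).
#' Set `averageSubFrames = TRUE` to instead average independently drawn
#' sub-frames (an alternative reading of shutter averaging; off by default).
#'
#' @param trajectory a [Trajectory-class]
#' @param config a [SceneConfig-class]
#' @param maps [CameraMaps-class] for the sCMOS camera
#' @param averageSubFrames average noisy sub-frames instead of rates
#' @return a [FrameStack-class] carrying the ground-truth frame positions
#' @export
renderStack <- function(trajectory, config, maps = NULL,
                        averageSubFrames = FALSE) {
  N <- config@nFrames
  P <- config@P
  nb <- nBlurSteps(config)
  out <- array(0, c(N, P, P))
  truth <- matrix(0, N, 2)
  origins <- matrix(0, N, 2)
  sub <- trajectory@subPositions
  centre <- c(P * config@dx / 2, P * config@dy / 2)
  px <- c(config@dx, config@dy)
  for (k in seq_len(N)) {
    idx <- (k - 1L) * config@nSub + seq_len(nb)
    # the position the frame actually encodes: the mean over the shutter
    truth[k, ] <- colMeans(sub[idx, , drop = FALSE])
    if (config@segmentation == "tracked") {
      # window centred on the frame-start position, snapped to whole pixels
      fs <- sub[idx[1], ]
      origins[k, ] <- round((fs - centre) / px) * px
    }
    rel <- sweep(sub[idx, , drop = FALSE], 2, origins[k, ])
    if (averageSubFrames && nb > 1L) {
      acc <- matrix(0, P, P)
      for (i in seq_len(nb)) {
        r <- expectedPixelRates(rel[i, ], config)
        acc <- acc + renderFrame(r, config, maps)
      }
      out[k, , ] <- acc / nb
    } else {
      r <- blurredRates(rel, config)
      out[k, , ] <- renderFrame(r, config, maps)
    }
  }
  frameStack(out, config, truth = truth, origins = origins)
}

#' Generate a reproducible set of simulated sequences
#'
#' Orchestrates [simulateTrajectory()] and [renderStack()] for `K`
#' independent sequences. Sequence `i` uses its own RNG substream seeded
#' `seed + i`, so the dataset is a pure function of `(config, seed)` and
#' individual sequences can be regenerated in isolation.
#'
#' @param config a [SceneConfig-class]
#' @param K number of sequences
#' @param seed master seed (keep `seed + K` below 2^31)
#' @param maps [CameraMaps-class] for the sCMOS camera
#' @param averageSubFrames see [renderStack()]
#' @return list of `K` elements, each `list(trajectory =, stack =)`
#' @export
generateDataset <- function(config, K, seed, maps = NULL,
                            averageSubFrames = FALSE) {
  if (config@cameraKind == "scmos" && is.null(maps))
    stop("camera maps are required for the sCMOS camera model")
  lapply(seq_len(K), function(i) {
    set.seed(seed + i)
    tr <- simulateTrajectory(config)
    list(trajectory = tr,
         stack = renderStack(tr, config, maps, averageSubFrames))
  })
}
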