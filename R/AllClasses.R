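#' @import methods
#' @importFrom stats pnorm rnorm rpois runif optim dpois optimize var sd
#'   median quantile qchisq dnorm integrate
#' @importFrom utils write.csv read.csv head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib sptEM, .registration = TRUE
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Scene configuration for simulation and inference
#'
#' Bundles the optical, detector, motion and acquisition parameters that
#' define one imaging condition: emission wavelength and numerical aperture
#' (from which the Gaussian PSF width defaults to
#' \eqn{\sigma = \sqrt{2}\lambda/(2\pi \mathrm{NA})}), the expected peak
#' signal photons per frame \code{G} and uniform background photons per pixel
#' per frame \code{Nbgd} (both already integrated over the shutter period),
#' the pixel grid, frame timing, the fine-grid sub-sampling factor used for
#' motion blur, and the per-axis diffusion coefficients.
#'
#' Continuous positions are in nanometres. Pixel \code{(i, j)} (0-based, row
#' \code{i} = y) covers the half-open box
#' \code{[j*dx, (j+1)*dx) x [i*dy, (i+1)*dy)}; the image origin is the
#' lower-left corner of pixel \code{(0, 0)} and the default initial particle
#' position is the field centre.
#'
#' @slot wavelength emission wavelength (nm)
#' @slot na numerical aperture (dimensionless)
#' @slot G expected photons per frame at the PSF peak
#' @slot Nbgd expected background photons per pixel per frame
#' @slot psfSigmaX,psfSigmaY Gaussian PSF widths (nm)
#' @slot P pixels per side of the segmented frame
#' @slot dx,dy pixel pitch (nm)
#' @slot dt frame interval (s)
#' @slot shutter shutter (photon accumulation) time (s)
#' @slot nFrames number of frames per sequence
#' @slot nSub sub-sampling factor for the fine motion grid
#' @slot Dx,Dy diffusion coefficients (um^2/s)
#' @slot cameraKind \code{"ideal"} or \code{"scmos"}
#' @slot segmentation \code{"tracked"} (each frame's window is centred on the
#'   particle's frame-start position, snapped to the pixel grid, emulating a
#'   segmentation step that follows the particle) or \code{"fixed"} (window
#'   anchored at the origin for the whole sequence)
#' @slot initialPosition length-2 numeric (nm), particle position at t = 0
#' @export
setClass("SceneConfig",
  representation(
    wavelength = "numeric", na = "numeric", G = "numeric", Nbgd = "numeric",
    psfSigmaX = "numeric", psfSigmaY = "numeric", P = "integer",
    dx = "numeric", dy = "numeric", dt = "numeric", shutter = "numeric",
    nFrames = "integer", nSub = "integer", Dx = "numeric", Dy = "numeric",
    cameraKind = "character", segmentation = "character",
    initialPosition = "numeric"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  chkPos <- function(val, name, strict = FALSE) {
    if (length(val) != 1 || !is.finite(val) || (strict && val <= 0) ||
        (!strict && val < 0))
      sprintf("'%s' must be a %s finite scalar", name,
              if (strict) "positive" else "nonnegative")
    else NULL
  }
  for (f in c("wavelength", "na", "dx", "dy", "dt"))
    msg <- c(msg, chkPos(slot(object, f), f, strict = TRUE))
  for (f in c("G", "Nbgd", "Dx", "Dy", "shutter", "psfSigmaX", "psfSigmaY"))
    msg <- c(msg, chkPos(slot(object, f), f))
  if (object@P < 3L) msg <- c(msg, "'P' must be >= 3 pixels")
  if (object@nFrames < 1L) msg <- c(msg, "'nFrames' must be >= 1")
  if (object@nSub < 1L) msg <- c(msg, "'nSub' must be >= 1")
  if (object@shutter > object@dt + 1e-12)
    msg <- c(msg, "'shutter' must not exceed the frame interval 'dt'")
  if (object@nSub > 1L && is.finite(object@dt) && object@dt > 0) {
    nb <- object@shutter / (object@dt / object@nSub)
    if (!is.finite(nb) || abs(nb - round(nb)) > 1e-9 || round(nb) < 1)
      msg <- c(msg, "'shutter' must span an integer number >= 1 of sub-steps")
  }
  if (!object@cameraKind %in% c("ideal", "scmos"))
    msg <- c(msg, "'cameraKind' must be \"ideal\" or \"scmos\"")
  if (!object@segmentation %in% c("tracked", "fixed"))
    msg <- c(msg, "'segmentation' must be \"tracked\" or \"fixed\"")
  if (length(object@initialPosition) != 2 ||
      any(!is.finite(object@initialPosition)))
    msg <- c(msg, "'initialPosition' must be a finite length-2 vector (nm)")
  if (length(msg)) msg else TRUE
})

#' Ground-truth particle trajectory
#'
#' Positions of the emitter on the fine sub-sampled time grid used for motion
#' blur, together with the frame-start positions (the hidden states the
#' estimators target). Increments of \code{subPositions} along each axis are
#' i.i.d. zero-mean Gaussian with variance \eqn{2 D \Delta t / N_{sub}}.
#'
#' @slot frameTimes frame start times (s), length N
#' @slot framePositions N x 2 matrix (nm), position at the start of each frame
#' @slot subPositions (N*Nsub) x 2 matrix (nm), fine-grid positions
#' @export
setClass("Trajectory",
  representation(frameTimes = "numeric", framePositions = "matrix",
                 subPositions = "matrix")
)

setValidity("Trajectory", function(object) {
  msg <- character()
  N <- length(object@frameTimes)
  if (!is.numeric(object@framePositions) || ncol(object@framePositions) != 2 ||
      nrow(object@framePositions) != N)
    msg <- c(msg, "'framePositions' must be an N x 2 numeric matrix")
  if (ncol(object@subPositions) != 2)
    msg <- c(msg, "'subPositions' must have 2 columns")
  if (nrow(object@subPositions) %% max(N, 1) != 0)
    msg <- c(msg, "'subPositions' rows must be a multiple of N")
  if (length(msg)) msg else TRUE
})

#' Per-pixel camera calibration maps
#'
#' Readout-noise variance \eqn{\sigma^2_p} (counts^2) and gain \eqn{g_p}
#' (counts/photon) for every pixel of the segmented field, as used by the
#' sCMOS measurement model. Both maps are treated as constant in time.
#'
#' @slot readoutVariance P x P matrix of positive per-pixel variances
#' @slot gain P x P matrix of positive per-pixel gains
#' @export
setClass("CameraMaps",
  representation(readoutVariance = "matrix", gain = "matrix")
)

setValidity("CameraMaps", function(object) {
  msg <- character()
  if (!all(dim(object@readoutVariance) == dim(object@gain)))
    msg <- c(msg, "variance and gain maps must have identical dimensions")
  if (any(object@readoutVariance <= 0) || any(!is.finite(object@readoutVariance)))
    msg <- c(msg, "'readoutVariance' must be strictly positive and finite")
  if (any(object@gain <= 0) || any(!is.finite(object@gain)))
    msg <- c(msg, "'gain' must be strictly positive and finite")
  if (length(msg)) msg else TRUE
})

#' A sequence of segmented camera frames
#'
#' The observations: N frames of P x P measured counts. Ideal-camera counts
#' are nonnegative integers (Poisson draws); sCMOS counts are real-valued
#' because of the additive Gaussian readout component.
#'
#' @slot frames numeric array N x P x P of measured counts
#' @slot config the [SceneConfig-class] the frames were generated/acquired under
#' @slot origins N x 2 matrix (nm): global position of each frame's window
#'   lower-left corner (all zero for a fixed window)
#' @slot truth optional N x 2 matrix of ground-truth positions (nm, global
#'   coordinates; the shutter-averaged position the frame encodes)
#' @export
setClass("FrameStack",
  representation(frames = "array", config = "SceneConfig",
                 origins = "matrix", truth = "matrixOrNULL")
)

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "'frames' must be an N x P x P array")
  else {
    if (d[2] != object@config@P || d[3] != object@config@P)
      msg <- c(msg, "frame dimensions do not match config 'P'")
    if (d[1] != object@config@nFrames)
      msg <- c(msg, "number of frames does not match config 'nFrames'")
    if (object@config@cameraKind == "ideal") {
      fr <- object@frames
      if (any(fr < 0) || any(abs(fr - round(fr)) > 1e-9))
        msg <- c(msg, "ideal-camera frames must hold nonnegative integers")
    }
  }
  if (!is.null(object@truth) &&
      (ncol(object@truth) != 2 || nrow(object@truth) != d[1]))
    msg <- c(msg, "'truth' must be an N x 2 matrix")
  if (length(d) == 3 &&
      (ncol(object@origins) != 2 || nrow(object@origins) != d[1]))
    msg <- c(msg, "'origins' must be an N x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' Smoothed posterior summary of the hidden trajectory
#'
#' E-step output: smoothed means, marginal covariances and lag-one
#' cross-covariances of the hidden positions given all frames, plus the
#' posterior of the pre-observation initial state \eqn{X_0}. The lag-one
#' blocks are \eqn{E[(X_t - m_t)(X_{t-1} - m_{t-1})' | Y_{1:N}]}, with the
#' first block pairing frame 1 with the initial state.
#'
#' @slot mean N x 2 smoothed means (nm)
#' @slot cov N x 2 x 2 smoothed covariances (nm^2)
#' @slot lagOneCov N x 2 x 2 lag-one cross-covariances when an initial state
#'   is present, otherwise (N-1) x 2 x 2
#' @slot initial list with elements \code{mean} (length 2) and \code{cov}
#'   (2 x 2) for \eqn{X_0}, or empty list if absent
#' @export
setClass("PosteriorTrajectory",
  representation(mean = "matrix", cov = "array", lagOneCov = "array",
                 initial = "list")
)

setValidity("PosteriorTrajectory", function(object) {
  msg <- character()
  N <- nrow(object@mean)
  if (ncol(object@mean) != 2) msg <- c(msg, "'mean' must be N x 2")
  if (!all(dim(object@cov) == c(N, 2, 2)))
    msg <- c(msg, "'cov' must be N x 2 x 2")
  nlag <- if (length(object@initial)) N else max(N - 1, 0)
  if (!all(dim(object@lagOneCov) == c(nlag, 2, 2)))
    msg <- c(msg, "'lagOneCov' has wrong dimensions")
  for (t in seq_len(N)) {
    S <- object@cov[t, , ]
    if (any(!is.finite(S)) || S[1, 1] < -1e-9 || S[2, 2] < -1e-9 ||
        abs(S[1, 2] - S[2, 1]) > 1e-6 * (1 + max(abs(S))))
      { msg <- c(msg, "smoothed covariances must be finite symmetric PSD"); break }
  }
  if (length(msg)) msg else TRUE
})

#' Result of an EM run
#'
#' Per-iteration trace of the diffusion-coefficient estimates, the final
#' estimate, the posterior trajectory at the final parameter, and run
#' diagnostics.
#'
#' @slot thetaTrace iterations x 2 matrix of (Dx, Dy) in um^2/s, first row is
#'   the initial value
#' @slot finalTheta named length-2 numeric (Dx, Dy)
#' @slot posterior [PosteriorTrajectory-class] at the final parameter
#' @slot backend backend tag ("u-em", "smc-em", "kalman")
#' @slot iterations number of EM iterations actually run
#' @slot failed TRUE if the smoothing backend diverged
#' @export
setClass("EMResult",
  representation(thetaTrace = "matrix", finalTheta = "numeric",
                 posterior = "PosteriorTrajectory", backend = "character",
                 iterations = "integer", failed = "logical")
)

setValidity("EMResult", function(object) {
  msg <- character()
  if (ncol(object@thetaTrace) != 2)
    msg <- c(msg, "'thetaTrace' must have 2 columns")
  if (!object@failed && any(object@thetaTrace < 0))
    msg <- c(msg, "'thetaTrace' entries must be nonnegative")
  if (length(object@finalTheta) != 2)
    msg <- c(msg, "'finalTheta' must have length 2")
  if (length(msg)) msg else TRUE
})
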