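#' Construct a scene configuration
#'
#' Defaults reproduce the package's reference imaging condition: a widefield
#' setup at 540 nm emission through an NA 1.2 objective (Gaussian PSF width
#' 101.3 nm), 25 x 25 pixels of 100 nm pitch, 100 frames at 10 frames/s with a
#' 10 ms shutter, a fine motion grid of 100 sub-steps per frame, peak signal
#' G = 100 photons/frame, background 10 photons/pixel/frame, and diffusion
#' Dx = 0.005, Dy = 0.01 um^2/s.
#'
#' @param wavelength emission wavelength (nm)
#' @param na numerical aperture
#' @param G expected photons per frame at the PSF peak (rate after shutter
#'   accumulation)
#' @param Nbgd expected background photons per pixel per frame
#' @param psfSigmaX,psfSigmaY PSF widths (nm); default derived from the optics
#'   via [psfSigmaFromOptics()]
#' @param P pixels per side
#' @param dx,dy pixel pitch (nm)
#' @param dt frame interval (s)
#' @param shutter photon accumulation time (s); must span a whole number of
#'   sub-steps when `nSub > 1`
#' @param nFrames frames per sequence
#' @param nSub sub-sampling factor of the fine motion grid (1 = no blur)
#' @param Dx,Dy diffusion coefficients (um^2/s)
#' @param cameraKind `"ideal"` (Poisson only) or `"scmos"` (Poisson plus
#'   pixel-dependent Gaussian readout)
#' @param segmentation `"tracked"` (default; each frame's window follows the
#'   particle, emulating per-frame segmentation) or `"fixed"`
#' @param initialPosition length-2 position (nm) at t = 0; default field centre
#' @return a validated [SceneConfig-class]
#' @examples
#' cfg <- sceneConfig()
#' cfg
#' @export
sceneConfig <- function(wavelength = 540, na = 1.2, G = 100, Nbgd = 10,
                        psfSigmaX = NULL, psfSigmaY = NULL, P = 25L,
                        dx = 100, dy = 100, dt = 0.1, shutter = 0.01,
                        nFrames = 100L, nSub = 100L, Dx = 0.005, Dy = 0.01,
                        cameraKind = c("ideal", "scmos"),
                        segmentation = c("tracked", "fixed"),
                        initialPosition = NULL) {
  cameraKind <- match.arg(cameraKind)
  segmentation <- match.arg(segmentation)
  sig <- psfSigmaFromOptics(wavelength, na)
  if (is.null(psfSigmaX)) psfSigmaX <- sig[[1]]
  if (is.null(psfSigmaY)) psfSigmaY <- sig[[2]]
  if (is.null(initialPosition)) initialPosition <- c(P * dx / 2, P * dy / 2)
  obj <- new("SceneConfig", wavelength = wavelength, na = na, G = G,
             Nbgd = Nbgd, psfSigmaX = psfSigmaX, psfSigmaY = psfSigmaY,
             P = as.integer(P), dx = dx, dy = dy, dt = dt, shutter = shutter,
             nFrames = as.integer(nFrames), nSub = as.integer(nSub),
             Dx = Dx, Dy = Dy, cameraKind = cameraKind,
             segmentation = segmentation,
             initialPosition = as.numeric(initialPosition))
  obj
}

#' Construct a frame stack
#'
#' @param frames N x P x P array of counts
#' @param config the [SceneConfig-class]
#' @param truth optional N x 2 ground-truth positions (nm, global)
#' @param origins N x 2 matrix of per-frame window origins (nm); default all
#'   zero (fixed window)
#' @return a [FrameStack-class]
#' @export
frameStack <- function(frames, config, truth = NULL, origins = NULL) {
  if (is.null(origins)) origins <- matrix(0, dim(frames)[1], 2)
  new("FrameStack", frames = frames, config = config, origins = origins,
      truth = truth)
}

#' Construct camera calibration maps
#'
#' @param readoutVariance P x P positive matrix (counts^2)
#' @param gain P x P positive matrix (counts/photon); default all 1
#' @return a [CameraMaps-class]
#' @export
cameraMaps <- function(readoutVariance,
                       gain = matrix(1, nrow(readoutVariance),
                                     ncol(readoutVariance))) {
  new("CameraMaps", readoutVariance = readoutVariance, gain = gain)
}

#' Construct a posterior trajectory summary
#'
#' @param mean N x 2 smoothed means (nm)
#' @param cov N x 2 x 2 smoothed covariances (nm^2)
#' @param lagOneCov lag-one cross-covariance blocks
#' @param initial list(mean, cov) posterior of the initial state, or list()
#' @return a [PosteriorTrajectory-class]
#' @export
posteriorTrajectory <- function(mean, cov, lagOneCov, initial = list()) {
  new("PosteriorTrajectory", mean = mean, cov = cov, lagOneCov = lagOneCov,
      initial = initial)
}

## ---- accessors ----

#' @rdname sptEM-accessors
#' @export
setMethod("frames", "FrameStack", function(object) object@frames)

#' @rdname sptEM-accessors
#' @export
setMethod("sceneConfigOf", "FrameStack", function(object) object@config)

#' @rdname sptEM-accessors
#' @export
setMethod("truePositions", "FrameStack", function(object) object@truth)

#' @rdname sptEM-accessors
#' @export
setMethod("windowOrigins", "FrameStack", function(object) object@origins)

#' @rdname sptEM-accessors
#' @export
setMethod("framePositions", "Trajectory", function(object) object@framePositions)

#' @rdname sptEM-accessors
#' @export
setMethod("subPositions", "Trajectory", function(object) object@subPositions)

#' @rdname sptEM-accessors
#' @export
setMethod("readoutVariance", "CameraMaps", function(object) object@readoutVariance)

#' @rdname sptEM-accessors
#' @export
setMethod("gainMap", "CameraMaps", function(object) object@gain)

#' @rdname sptEM-accessors
#' @export
setMethod("smoothedMean", "PosteriorTrajectory", function(object) object@mean)

#' @rdname sptEM-accessors
#' @export
setMethod("smoothedCov", "PosteriorTrajectory", function(object) object@cov)

#' @rdname sptEM-accessors
#' @export
setMethod("lagOneCov", "PosteriorTrajectory", function(object) object@lagOneCov)

#' @rdname sptEM-accessors
#' @export
setMethod("initialState", "PosteriorTrajectory", function(object) object@initial)

#' @rdname sptEM-accessors
#' @export
setMethod("thetaTrace", "EMResult", function(object) object@thetaTrace)

#' @rdname sptEM-accessors
#' @export
setMethod("finalTheta", "EMResult", function(object) object@finalTheta)

#' @rdname sptEM-accessors
#' @export
setMethod("posteriorOf", "EMResult", function(object) object@posterior)

#' @rdname sptEM-accessors
#' @export
setMethod("emFailed", "EMResult", function(object) object@failed)

## ---- show methods ----

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@cameraKind, "camera\n")
  cat(sprintf("  optics: lambda = %g nm, NA = %g, PSF sigma = (%.1f, %.1f) nm\n",
              object@wavelength, object@na, object@psfSigmaX, object@psfSigmaY))
  cat(sprintf("  field:  %d x %d px of %g x %g nm\n", object@P, object@P,
              object@dx, object@dy))
  cat(sprintf("  frames: N = %d, dt = %g s, shutter = %g s, nSub = %d\n",
              object@nFrames, object@dt, object@shutter, object@nSub))
  cat(sprintf("  rates:  G = %g, Nbgd = %g photons/frame\n",
              object@G, object@Nbgd))
  cat(sprintf("  motion: Dx = %g, Dy = %g um^2/s\n", object@Dx, object@Dy))
})

setMethod("show", "Trajectory", function(object) {
  N <- length(object@frameTimes)
  cat(sprintf("Trajectory: %d frames, %d sub-steps\n", N,
              nrow(object@subPositions)))
  if (N > 0)
    cat(sprintf("  start (%.1f, %.1f) nm, end (%.1f, %.1f) nm\n",
                object@framePositions[1, 1], object@framePositions[1, 2],
                object@framePositions[N, 1], object@framePositions[N, 2]))
})

setMethod("show", "CameraMaps", function(object) {
  cat(sprintf("CameraMaps: %d x %d px\n", nrow(object@readoutVariance),
              ncol(object@readoutVariance)))
  cat(sprintf("  readout variance: mean %.3g counts^2 (range %.3g-%.3g)\n",
              mean(object@readoutVariance), min(object@readoutVariance),
              max(object@readoutVariance)))
  cat(sprintf("  gain: mean %.3g counts/photon\n", mean(object@gain)))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px (%s camera)%s\n",
              d[1], d[2], d[3], object@config@cameraKind,
              if (is.null(object@truth)) "" else ", with ground truth"))
})

setMethod("show", "PosteriorTrajectory", function(object) {
  N <- nrow(object@mean)
  cat(sprintf("PosteriorTrajectory over %d frames%s\n", N,
              if (length(object@initial)) " (+ initial state)" else ""))
  if (N > 0)
    cat(sprintf("  mean marginal std: (%.1f, %.1f) nm\n",
                sqrt(mean(object@cov[, 1, 1])), sqrt(mean(object@cov[, 2, 2]))))
})

setMethod("show", "EMResult", function(object) {
  cat(sprintf("EMResult [%s]: %d iterations%s\n", object@backend,
              object@iterations, if (object@failed) " (FAILED)" else ""))
  cat(sprintf("  final Dx = %.4g, Dy = %.4g um^2/s\n",
              object@finalTheta[1], object@finalTheta[2]))
})
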