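#' Pixel-wise observation log-likelihood of a frame
#'
#' Log-probability of one segmented frame given a candidate emitter position.
#' Ideal camera: sum of Poisson log-pmfs with per-pixel means
#' \eqn{\lambda_p(x) + N_{bgd}} (\eqn{-\infty} is possible for impossible
#' counts at zero rate). sCMOS camera: sum of log Poisson-Gaussian
#' convolution densities (see [scmosPixelDensity()]) using the per-pixel
#' readout variance and gain.
#'
#' @param frame P x P matrix of measured counts
#' @param state length-2 position (nm), or k x 2 matrix for a batch
#' @param config a [SceneConfig-class]
#' @param maps [CameraMaps-class], required for the sCMOS camera
#' @param origin length-2 global position (nm) of the frame window's
#'   lower-left corner (zero for a fixed window)
#' @return numeric log-likelihood (length k)
#' @export
pixelLogLikelihood <- function(frame, state, config, maps = NULL,
                               origin = c(0, 0)) {
  st <- rbind(state)
  st <- cbind(st[, 1] - origin[1], st[, 2] - origin[2])
  I <- as.vector(frame)
  if (config@cameraKind == "scmos" || !is.null(maps)) {
    if (is.null(maps)) stop("camera maps are required for the sCMOS camera")
    pixelLogLikScmosCpp(I, st[, 1], st[, 2], config@G, config@Nbgd,
                        as.vector(readoutVariance(maps)),
                        as.vector(gainMap(maps)),
                        config@psfSigmaX, config@psfSigmaY,
                        config@P, config@dx, config@dy)
  } else {
    pixelLogLikIdealCpp(I, st[, 1], st[, 2], config@G, config@Nbgd,
                        config@psfSigmaX, config@psfSigmaY,
                        config@P, config@dx, config@dy)
  }
}

## systematic resampling: n indices from normalized weights w
systematicResample <- function(w, n = length(w)) {
  u <- (runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w)) + 1L
}

#' Bootstrap particle filter on raw pixel likelihoods
#'
#' Sequential importance sampling with the diffusion prior as proposal:
#' particles are propagated by the random-walk dynamics and reweighted by
#' [pixelLogLikelihood()] (log-sum-exp normalized). Systematic resampling is
#' triggered when the effective sample size falls below
#' `resampleThreshold * nParticles`. The stored clouds are the weighted
#' (pre-resampling) filtering representations, including the prior cloud at
#' t = 0; these are what the smoother consumes.
#'
#' @param stack a [FrameStack-class]
#' @param theta length-2 diffusion coefficients (um^2/s)
#' @param nParticles number of Monte Carlo samples (>= 2)
#' @param prior list(mean, cov) for the initial state X_0
#' @param maps [CameraMaps-class] for the sCMOS camera
#' @param resampleThreshold ESS fraction triggering resampling (default 0.5)
#' @param logLikFun optional replacement observation model,
#'   `function(t, states)` returning per-particle log-likelihoods for frame
#'   `t`; used to validate the filter against closed-form models
#' @return list with `xs`, `ys` (nParticles x (N+1) positions), `w`
#'   (normalized weights), `ess`, `resampled`, `ok`
#' @export
particleFilter <- function(stack, theta, nParticles, prior, maps = NULL,
                           resampleThreshold = 0.5, logLikFun = NULL) {
  if (nParticles < 2) stop("'nParticles' must be >= 2")
  cfg <- sceneConfigOf(stack)
  fr <- frames(stack)
  org <- windowOrigins(stack)
  N <- dim(fr)[1]
  Np <- as.integer(nParticles)
  qsd <- sqrt(2 * pmax(theta, 0) * 1e6 * cfg@dt)
  xs <- matrix(0, Np, N + 1)
  ys <- matrix(0, Np, N + 1)
  w <- matrix(0, Np, N + 1)
  ess <- numeric(N + 1)
  resampled <- logical(N + 1)
  # prior cloud at t = 0
  A <- t(chol(prior$cov + diag(1e-9, 2)))
  z <- matrix(rnorm(2 * Np), 2, Np)
  pts <- prior$mean + A %*% z
  xs[, 1] <- pts[1, ]
  ys[, 1] <- pts[2, ]
  w[, 1] <- 1 / Np
  ess[1] <- Np
  curX <- xs[, 1]; curY <- ys[, 1]; curW <- w[, 1]
  ok <- TRUE
  for (t in seq_len(N)) {
    px <- curX + rnorm(Np, 0, qsd[1])
    py <- curY + rnorm(Np, 0, qsd[2])
    ll <- if (is.null(logLikFun))
      pixelLogLikelihood(fr[t, , ], cbind(px, py), cfg, maps,
                         origin = org[t, ])
    else logLikFun(t, cbind(px, py))
    lw <- log(curW) + ll
    mx <- max(lw)
    if (!is.finite(mx)) { ok <- FALSE; break }
    wt <- exp(lw - mx)
    wt <- wt / sum(wt)
    xs[, t + 1] <- px; ys[, t + 1] <- py; w[, t + 1] <- wt
    ess[t + 1] <- 1 / sum(wt^2)
    if (ess[t + 1] < resampleThreshold * Np) {
      idx <- systematicResample(wt, Np)
      curX <- px[idx]; curY <- py[idx]; curW <- rep(1 / Np, Np)
      resampled[t + 1] <- TRUE
    } else {
      curX <- px; curY <- py; curW <- wt
    }
  }
  list(xs = xs, ys = ys, w = w, ess = ess, resampled = resampled, ok = ok,
       theta = theta, dt = cfg@dt)
}

#' Forward-filter backward-smoother over particle clouds
#'
#' FFBS reweighting (O(nParticles^2) per step) over the stored weighted
#' clouds of [particleFilter()]: backward recursion of smoothed marginal
#' weights plus pairwise weights, from which smoothed means, covariances and
#' the lag-one cross-covariances required by the EM M-step are computed.
#'
#' @param pf result of [particleFilter()]
#' @param theta length-2 diffusion coefficients (um^2/s); defaults to the
#'   value used in the filter pass
#' @param dt frame interval (s); defaults to the filter's
#' @return a [PosteriorTrajectory-class] with the initial state at t = 0 and
#'   attribute `weights` (smoothed weight matrix)
#' @export
particleSmoother <- function(pf, theta = pf$theta, dt = pf$dt) {
  if (!isTRUE(pf$ok)) stop("cannot smooth a failed filter pass")
  qx <- 2 * max(theta[1], 0) * 1e6 * dt
  qy <- 2 * max(theta[2], 0) * 1e6 * dt
  res <- ffbsCpp(pf$xs, pf$ys, pf$w, qx, qy)
  N <- ncol(pf$xs) - 1L
  cov <- array(0, c(N, 2, 2))
  cov[, 1, 1] <- res$cov[-1, 1]
  cov[, 2, 2] <- res$cov[-1, 2]
  cov[, 1, 2] <- res$cov[-1, 3]
  cov[, 2, 1] <- res$cov[-1, 3]
  lag <- array(0, c(N, 2, 2))
  lag[, 1, 1] <- res$lag[, 1]
  lag[, 2, 2] <- res$lag[, 2]
  lag[, 1, 2] <- res$lag[, 3]
  lag[, 2, 1] <- res$lag[, 4]
  out <- posteriorTrajectory(
    mean = res$mean[-1, , drop = FALSE],
    cov = cov, lagOneCov = lag,
    initial = list(mean = res$mean[1, ],
                   cov = matrix(c(res$cov[1, 1], res$cov[1, 3],
                                  res$cov[1, 3], res$cov[1, 2]), 2, 2)))
  attr(out, "weights") <- res$weights
  attr(out, "degenerate") <- res$degenerate
  out
}

#' SMC-EM smoothing backend
#'
#' E-step backend for [runEM()]: bootstrap particle filter on the raw pixel
#' likelihood followed by FFBS smoothing.
#'
#' @param nParticles Monte Carlo samples in filter and smoother (default 500)
#' @param resampleThreshold ESS fraction triggering resampling
#' @return backend object for [runEM()]
#' @export
smcEmBackend <- function(nParticles = 500, resampleThreshold = 0.5) {
  structure(list(
    tag = sprintf("smc-em^%d", as.integer(nParticles)),
    smooth = function(obs, theta, prior, config, maps = NULL, dt) {
      pf <- particleFilter(obs, theta, nParticles, prior, maps,
                           resampleThreshold)
      if (!pf$ok) return(list(posterior = NULL, ok = FALSE))
      list(posterior = particleSmoother(pf, theta, dt), ok = TRUE)
    }), class = "sptemBackend")
}
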