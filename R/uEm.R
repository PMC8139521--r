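#' UKF sigma-point settings
#'
#' Spread parameters of the unscented transform and the covariance jitter
#' floor. Defaults `alpha = 1, beta = 2, kappa = 1` give
#' \eqn{\lambda = \alpha^2(n+\kappa) - n = 1} for the 2-D state.
#'
#' @param alpha primary spread parameter
#' @param beta distribution parameter (2 is optimal for Gaussians)
#' @param kappa secondary spread parameter
#' @param jitter diagonal jitter (nm^2) added before Cholesky factorization
#' @return list of settings for [ukfFilter()]
#' @export
ukfSettings <- function(alpha = 1, beta = 2, kappa = 1, jitter = 1e-12) {
  n <- 2
  lam <- alpha^2 * (n + kappa) - n
  wm <- c(lam / (n + lam), rep(1 / (2 * (n + lam)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  stopifnot(abs(sum(wm) - 1) < 1e-12)
  list(alpha = alpha, beta = beta, kappa = kappa, lambda = lam,
       wm = wm, wc = wc, jitter = jitter)
}

#' Anscombe variance-stabilizing transform of a frame stack
#'
#' Maps approximately Poisson counts (plus optional Gaussian readout noise of
#' per-pixel variance \eqn{\sigma^2_p}) to approximately unit-variance
#' Gaussian data: \eqn{\tilde I = 2\sqrt{I + 3/8 + \sigma^2}}. With gain maps
#' present the counts and readout variance are first referred to photon units
#' (\eqn{I/g}, \eqn{\sigma^2/g^2}). Negative arguments (possible for sCMOS
#' frames) are clipped at zero before the square root; the number of clipped
#' pixels is recorded in attribute `nClipped`.
#'
#' @param stack a [FrameStack-class]
#' @param maps optional [CameraMaps-class]
#' @return N x P x P numeric array of transformed frames
#' @export
anscombeTransform <- function(stack, maps = NULL) {
  fr <- frames(stack)
  N <- dim(fr)[1]
  if (is.null(maps)) {
    arg <- fr + 3 / 8
  } else {
    g <- gainMap(maps)
    s2 <- readoutVariance(maps) / g^2
    arg <- fr
    for (t in seq_len(N)) arg[t, , ] <- fr[t, , ] / g + s2 + 3 / 8
  }
  ncl <- sum(arg < 0)
  out <- 2 * sqrt(pmax(arg, 0))
  attr(out, "nClipped") <- ncl
  out
}

#' Deterministic part of the transformed pixel observation
#'
#' The measurement function used by the UKF: for a particle at `state`, the
#' Anscombe-scale prediction for every pixel,
#' \eqn{h_p(x) = 2\sqrt{\lambda_p(x) + N_{bgd} + 3/8 + \sigma_p^2/g_p^2}},
#' stacked in column-major pixel order. The background rate is part of the
#' Poisson mean and is therefore included under the square root.
#'
#' @param state length-2 position (nm, window coordinates)
#' @param config a [SceneConfig-class]
#' @param maps optional [CameraMaps-class]
#' @return numeric vector of length P^2
#' @export
ukfTransformedObservation <- function(state, config, maps = NULL) {
  pixelObsFun(config, maps)(rbind(state), 1L)[, 1]
}

## batched measurement function factory: (states (k x 2 global nm), frame t)
## -> P^2 x k matrix; origins shift global coordinates into each frame's
## segmentation window
pixelObsFun <- function(config, maps = NULL, origins = NULL) {
  s2g <- if (is.null(maps)) 0 else
    as.vector(readoutVariance(maps) / gainMap(maps)^2)
  function(states, t) {
    o <- if (is.null(origins)) c(0, 0) else origins[t, ]
    lam <- rateMapBatchCpp(states[, 1] - o[1], states[, 2] - o[2], config@G,
                           config@psfSigmaX, config@psfSigmaY,
                           config@P, config@dx, config@dy)
    2 * sqrt(lam + config@Nbgd + 3 / 8 + s2g)
  }
}

## sigma points for 2-D mean m, covariance P (list: matrix 2 x 5)
sigmaPoints <- function(m, Pm, settings) {
  n <- 2
  A <- tryCatch(t(chol((n + settings$lambda) *
                         (Pm + diag(settings$jitter, 2)))),
                error = function(e) NULL)
  if (is.null(A)) return(NULL)
  cbind(m, m + A[, 1], m + A[, 2], m - A[, 1], m - A[, 2])
}

## apply inv(S) to columns of X where S = diag(r) + U U', via Woodbury
woodburySolve <- function(U, r, X) {
  Xr <- X / r
  Ur <- U / r
  M <- diag(ncol(U)) + crossprod(U, Ur)
  Xr - Ur %*% solve(M, crossprod(U, Xr))
}

#' Unscented Kalman filter for the tracking state-space model
#'
#' Additive-noise UKF on the 2-D position state with random-walk dynamics of
#' per-axis process variance \eqn{2 D \Delta t} (exact linear prediction) and
#' a nonlinear measurement function evaluated through sigma points. The
#' measurement-noise covariance is diagonal (unit variance on the Anscombe
#' scale by default); the innovation covariance is low-rank plus diagonal and
#' is inverted by the matrix-inversion lemma, so the cost per frame is linear
#' in the number of pixels.
#'
#' @param obs N x m matrix of observation vectors (transformed counts, or any
#'   injected observation model)
#' @param theta length-2 diffusion coefficients (um^2/s)
#' @param dt frame interval (s)
#' @param prior list(mean, cov) for the initial state X_0
#' @param obsFun batched measurement function `(states, t)`: k x 2 states and
#'   the frame index -> m x k matrix (time dependence carries the per-frame
#'   segmentation-window origins)
#' @param settings [ukfSettings()]
#' @param Rdiag measurement-noise variance, scalar or length-m (default 1)
#' @return list with filtered means/covariances (`mf`, `Pf`, including the
#'   t = 0 prior), predicted covariances (`Pp`), and `ok` flag; `ok = FALSE`
#'   signals loss of positive definiteness (the expected failure mode at
#'   large diffusion coefficients)
#' @export
ukfFilter <- function(obs, theta, dt, prior, obsFun,
                      settings = ukfSettings(), Rdiag = 1) {
  obs <- rbind(obs)
  N <- nrow(obs)
  m <- ncol(obs)
  r <- if (length(Rdiag) == 1) rep(Rdiag, m) else Rdiag
  qd <- 2 * pmax(theta, 0) * 1e6 * dt
  Q <- diag(qd, 2)
  mf <- matrix(0, N + 1, 2)
  Pf <- array(0, c(N + 1, 2, 2))
  Pp <- array(0, c(N + 1, 2, 2))
  mf[1, ] <- prior$mean
  Pf[1, , ] <- prior$cov
  wm <- settings$wm
  wc <- settings$wc
  ok <- TRUE
  for (t in seq_len(N)) {
    mpred <- mf[t, ]
    Ppred <- Pf[t, , ] + Q
    Pp[t + 1, , ] <- Ppred
    chi <- sigmaPoints(mpred, Ppred, settings)
    if (is.null(chi)) { ok <- FALSE; break }
    Y <- obsFun(t(chi), t)                   # m x 5
    yhat <- as.vector(Y %*% wm)
    Yd <- Y - yhat
    Xd <- chi - mpred
    Pxy <- Xd %*% (wc * t(Yd))               # 2 x m
    innov <- obs[t, ] - yhat
    if (all(wc >= 0)) {
      U <- Yd * rep(sqrt(wc), each = m)      # m x 5, S = diag(r) + U U'
      sol <- woodburySolve(U, r, cbind(innov, t(Pxy)))
    } else {
      S <- diag(r, m) + Yd %*% (wc * t(Yd))
      sol <- solve(S, cbind(innov, t(Pxy)))
    }
    mnew <- mpred + as.vector(Pxy %*% sol[, 1])
    Pnew <- Ppred - Pxy %*% sol[, 2:3]
    Pnew <- (Pnew + t(Pnew)) / 2
    if (any(!is.finite(mnew)) || any(!is.finite(Pnew)) ||
        min(eigen(Pnew, symmetric = TRUE, only.values = TRUE)$values) <
          -1e-6 * max(abs(Pnew), 1)) { ok <- FALSE; break }
    mf[t + 1, ] <- mnew
    Pf[t + 1, , ] <- Pnew + diag(settings$jitter, 2)
  }
  list(mf = mf, Pf = Pf, Pp = Pp, N = N, ok = ok)
}

#' Unscented Rauch-Tung-Striebel smoother
#'
#' Backward pass over a [ukfFilter()] result. The dynamics are linear
#' (identity plus noise), for which the unscented time-update statistics are
#' exact, so the smoother gain is \eqn{G_t = P_{t|t} P_{t+1|t}^{-1}}; the
#' lag-one cross-covariances follow the standard identity
#' \eqn{C_{t+1,t|N} = P_{t+1|N} G_t'}.
#'
#' @param filterOut result of [ukfFilter()]
#' @return a [PosteriorTrajectory-class] (with the initial state at t = 0)
#' @export
urtssSmooth <- function(filterOut) {
  if (!isTRUE(filterOut$ok)) stop("cannot smooth a failed filter pass")
  N <- filterOut$N
  mf <- filterOut$mf
  Pf <- filterOut$Pf
  Pp <- filterOut$Pp
  ms <- mf
  Ps <- Pf
  Cl <- array(0, c(N, 2, 2))
  for (t in N:1) {
    G <- t(solve(Pp[t + 1, , ], Pf[t, , ]))
    ms[t, ] <- mf[t, ] + as.vector(G %*% (ms[t + 1, ] - mf[t, ]))
    Pn <- Pf[t, , ] + G %*% (Ps[t + 1, , ] - Pp[t + 1, , ]) %*% t(G)
    Ps[t, , ] <- (Pn + t(Pn)) / 2
    Cl[t, , ] <- Ps[t + 1, , ] %*% t(G)
  }
  posteriorTrajectory(mean = ms[-1, , drop = FALSE],
                      cov = Ps[-1, , , drop = FALSE],
                      lagOneCov = Cl,
                      initial = list(mean = ms[1, ], cov = Ps[1, , ]))
}

#' U-EM smoothing backend
#'
#' E-step backend for [runEM()]: Anscombe-transforms the frames, runs the
#' unscented Kalman filter with unit measurement variance, and smooths with
#' the unscented RTS recursion.
#'
#' @param settings [ukfSettings()]
#' @return backend object for [runEM()]
#' @export
uEmBackend <- function(settings = ukfSettings()) {
  structure(list(
    tag = "u-em",
    smooth = function(obs, theta, prior, config, maps = NULL, dt) {
      tf <- anscombeTransform(obs, maps)
      N <- dim(tf)[1]
      y <- matrix(tf, N, config@P^2)   # column-major pixel flattening
      h <- pixelObsFun(config, maps, windowOrigins(obs))
      flt <- ukfFilter(y, theta, dt, prior, h, settings, Rdiag = 1)
      if (!flt$ok) return(list(posterior = NULL, ok = FALSE))
      list(posterior = urtssSmooth(flt), ok = TRUE)
    }), class = "sptemBackend")
}
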