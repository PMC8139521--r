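#' Closed-form M-step for the diffusion coefficients
#'
#' Maximizes the expected complete-data log-likelihood of the Gaussian
#' increments over D per axis. With smoothed means \eqn{m_t}, marginal
#' variances \eqn{P_t} and lag-one covariances \eqn{C_{t,t-1}},
#' \deqn{\hat D_a = \frac{1}{2 n \Delta t} \sum_t \left[(m_{t,a} -
#'   m_{t-1,a})^2 + P_{t,aa} + P_{t-1,aa} - 2 C_{t,t-1,aa}\right],}
#' summing over the `n` available increments (including the initial-state
#' increment when the posterior carries one). The result is clamped at a tiny
#' positive floor.
#'
#' @param posterior a [PosteriorTrajectory-class] (nm scale)
#' @param dt frame interval (s)
#' @return named numeric `c(Dx, Dy)` in um^2/s
#' @export
mStepDiffusion <- function(posterior, dt) {
  m <- smoothedMean(posterior)
  S <- smoothedCov(posterior)
  C <- lagOneCov(posterior)
  N <- nrow(m)
  init <- initialState(posterior)
  if (length(init)) {
    mPrev <- rbind(init$mean, m[-N, , drop = FALSE])
    vPrev <- rbind(c(init$cov[1, 1], init$cov[2, 2]),
                   cbind(S[-N, 1, 1], S[-N, 2, 2]))
    mCur <- m
    vCur <- cbind(S[, 1, 1], S[, 2, 2])
  } else {
    if (N < 2) stop("at least two frames are required")
    mPrev <- m[-N, , drop = FALSE]
    vPrev <- cbind(S[-N, 1, 1], S[-N, 2, 2])
    mCur <- m[-1, , drop = FALSE]
    vCur <- cbind(S[-1, 1, 1], S[-1, 2, 2])
  }
  nInc <- nrow(mCur)
  cl <- cbind(C[, 1, 1], C[, 2, 2])
  ssq <- colSums((mCur - mPrev)^2 + vCur + vPrev - 2 * cl)
  D <- pmax(ssq / (2 * nInc * dt), 1e-12) * 1e-6  # nm^2/s -> um^2/s
  names(D) <- c("Dx", "Dy")
  D
}

## Exact linear-Gaussian RTS smoother for X_t = X_{t-1} + w, y_t = X_t + v.
## y: N x 2 (nm); qd: length-2 per-step process variances (nm^2);
## Rd: length-2 observation variances (nm^2); prior: list(mean, cov) for X_0.
kalmanSmoothLinear <- function(y, qd, Rd, prior) {
  N <- nrow(y)
  Q <- diag(qd, 2)
  R <- diag(Rd, 2)
  mf <- matrix(0, N + 1, 2)
  Pf <- array(0, c(N + 1, 2, 2))
  mp <- matrix(0, N + 1, 2)
  Pp <- array(0, c(N + 1, 2, 2))
  mf[1, ] <- prior$mean
  Pf[1, , ] <- prior$cov
  ll <- 0
  for (t in seq_len(N)) {
    mpred <- mf[t, ]
    Ppred <- Pf[t, , ] + Q
    S <- Ppred + R
    innov <- y[t, ] - mpred
    ll <- ll - 0.5 * (log(det(2 * pi * S)) +
                        sum(innov * solve(S, innov)))
    K <- t(solve(S, Ppred))           # Ppred %*% solve(S), S symmetric
    mf[t + 1, ] <- mpred + K %*% innov
    Pn <- Ppred - K %*% Ppred
    Pf[t + 1, , ] <- (Pn + t(Pn)) / 2
    mp[t + 1, ] <- mpred
    Pp[t + 1, , ] <- Ppred
  }
  ms <- mf
  Ps <- Pf
  Cl <- array(0, c(N, 2, 2))
  for (t in N:1) {
    G <- t(solve(Pp[t + 1, , ], Pf[t, , ]))   # Pf %*% solve(Pp)
    ms[t, ] <- mf[t, ] + G %*% (ms[t + 1, ] - mp[t + 1, ])
    Pn <- Pf[t, , ] + G %*% (Ps[t + 1, , ] - Pp[t + 1, , ]) %*% t(G)
    Ps[t, , ] <- (Pn + t(Pn)) / 2
    Cl[t, , ] <- Ps[t + 1, , ] %*% t(G)
  }
  list(posterior = posteriorTrajectory(
         mean = ms[-1, , drop = FALSE],
         cov = Ps[-1, , , drop = FALSE],
         lagOneCov = Cl,
         initial = list(mean = ms[1, ], cov = Ps[1, , ])),
       logLik = ll)
}

#' Exact log-likelihood of a linear-Gaussian tracking model
#'
#' Kalman-filter evaluation of \eqn{\log p_\theta(y_{1:N})} for the direct
#' position-observation model \eqn{X_t = X_{t-1} + w}, \eqn{y_t = X_t + v},
#' with \eqn{X_0} from a Gaussian prior. Used to verify EM monotonicity.
#'
#' @param y N x 2 observations (nm)
#' @param theta length-2 diffusion coefficients (um^2/s)
#' @param Rd length-2 observation-noise variances (nm^2)
#' @param prior list(mean, cov) for the initial state
#' @param dt frame interval (s)
#' @return scalar log-likelihood
#' @export
linearGaussianLogLik <- function(y, theta, Rd, prior, dt) {
  qd <- 2 * theta * 1e6 * dt
  kalmanSmoothLinear(y, qd, Rd, prior)$logLik
}

#' Exact-Kalman smoothing backend for linear test models
#'
#' E-step backend for [runEM()] operating on direct noisy position
#' observations (an N x 2 matrix) with known observation-noise variances.
#' This is the closed-form reference on which the nonlinear backends are
#' validated.
#'
#' @param Rd length-2 observation-noise variances (nm^2)
#' @return backend object for [runEM()]
#' @export
kalmanBackend <- function(Rd) {
  structure(list(
    tag = "kalman",
    smooth = function(obs, theta, prior, config = NULL, maps = NULL, dt) {
      qd <- 2 * theta * 1e6 * dt
      res <- kalmanSmoothLinear(rbind(obs), qd, Rd, prior)
      list(posterior = res$posterior, ok = TRUE)
    }), class = "sptemBackend")
}

#' Run the EM loop for diffusion-coefficient estimation
#'
#' Alternates an E-step (delegated to the smoothing backend: [uEmBackend()],
#' [smcEmBackend()], or [kalmanBackend()] for linear test models) with the
#' closed-form M-step [mStepDiffusion()]. Stops after `maxIter` iterations or
#' when the relative parameter change drops below `tol`. Only
#' \eqn{(D_x, D_y)} are estimated; the signal and background rates are
#' treated as known and the initial-state prior is held fixed.
#'
#' @param obs a [FrameStack-class] (image backends) or an N x 2 position
#'   matrix (kalman backend)
#' @param backend smoothing backend object
#' @param theta0 initial `c(Dx, Dy)` (um^2/s); default: Gaussian fitting plus
#'   MSD on the same frames
#' @param maxIter maximum EM iterations (default 10)
#' @param tol relative-change early-stopping tolerance; set 0 to disable
#' @param prior list(mean, cov) for the initial state X_0; default: Gaussian
#'   at the first-frame localization with 100 nm per-axis standard deviation
#' @param maps [CameraMaps-class] for sCMOS frames
#' @param dt frame interval (s); taken from the stack's config when omitted
#' @return an [EMResult-class]
#' @export
runEM <- function(obs, backend, theta0 = NULL, maxIter = 10L, tol = 1e-4,
                  prior = NULL, maps = NULL, dt = NULL) {
  isStack <- is(obs, "FrameStack")
  cfg <- if (isStack) sceneConfigOf(obs) else NULL
  if (is.null(dt)) {
    if (is.null(cfg)) stop("'dt' is required for matrix observations")
    dt <- cfg@dt
  }
  if (isStack && (is.null(theta0) || is.null(prior))) {
    scmos <- cfg@cameraKind == "scmos"
    loc <- if (scmos)
      localizeStack(obs, "mle-scmos", maps = maps, gate = 4 * cfg@dx)
    else localizeStack(obs, "gf")
    if (is.null(theta0)) {
      pos <- as.matrix(loc[, c("x", "y")])
      theta0 <- c(fitMsd(msdCurve(pos[, 1]), dt)$D,
                  fitMsd(msdCurve(pos[, 2]), dt)$D)
      theta0 <- pmax(theta0, 1e-6)
    }
    if (is.null(prior))
      prior <- list(mean = c(loc$x[1], loc$y[1]), cov = diag(100^2, 2))
  }
  if (is.null(theta0) || is.null(prior))
    stop("'theta0' and 'prior' are required for matrix observations")
  theta <- pmax(as.numeric(theta0), 1e-12)
  trace <- matrix(theta, 1, 2)
  posterior <- NULL
  failed <- FALSE
  iters <- 0L
  for (e in seq_len(maxIter)) {
    sm <- backend$smooth(obs, theta, prior, config = cfg, maps = maps,
                         dt = dt)
    if (!isTRUE(sm$ok)) { failed <- TRUE; break }
    posterior <- sm$posterior
    thetaNew <- mStepDiffusion(posterior, dt)
    iters <- e
    trace <- rbind(trace, thetaNew)
    rel <- max(abs(thetaNew - theta) / pmax(theta, 1e-12))
    theta <- as.numeric(thetaNew)
    if (tol > 0 && rel < tol) break
  }
  if (is.null(posterior))
    posterior <- posteriorTrajectory(
      mean = matrix(NA_real_, 0, 2), cov = array(0, c(0, 2, 2)),
      lagOneCov = array(0, c(0, 2, 2)), initial = list())
  rownames(trace) <- NULL
  new("EMResult", thetaTrace = trace,
      finalTheta = c(Dx = theta[1], Dy = theta[2]),
      posterior = posterior, backend = backend$tag,
      iterations = iters, failed = failed)
}
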