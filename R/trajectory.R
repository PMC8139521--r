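#' Mean square displacement curve of a 1-D position series
#'
#' \deqn{\mathrm{MSD}(n) = \frac{1}{N-n}\sum_{i=1}^{N-n}(r_{i+n}-r_i)^2,
#'   \quad n = 1, \dots, N-1.}
#'
#' @param positions numeric vector of length N >= 2 (nm)
#' @return list with `lags` (1..N-1) and `values` (nm^2)
#' @export
msdCurve <- function(positions) {
  N <- length(positions)
  if (N < 2) stop("at least two positions are required")
  vals <- vapply(seq_len(N - 1), function(n) {
    d <- positions[(n + 1):N] - positions[1:(N - n)]
    mean(d^2)
  }, 0)
  list(lags = seq_len(N - 1), values = vals)
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Least-squares fit of the free-diffusion model
#' \eqn{\mathrm{MSD}(n) = 2 D n \Delta t} (no offset) over lags
#' `1..maxLag`. All lags are used by default. The model is linear in D, so
#' the least-squares optimum is the closed-form no-intercept regression
#' slope; D is clamped at zero.
#'
#' @param curve list as returned by [msdCurve()] (values in nm^2)
#' @param dt frame interval (s)
#' @param maxLag largest lag to use; `Inf` (default) uses all
#' @return list with `D` (um^2/s), `method = "msd"`, and `residual`
#'   (root-mean-square fit residual, nm^2)
#' @export
fitMsd <- function(curve, dt, maxLag = Inf) {
  keep <- curve$lags <= maxLag
  n <- curve$lags[keep]
  v <- curve$values[keep]
  slope <- sum(n * v) / sum(n^2)          # nm^2 per lag
  D <- max(slope / (2 * dt), 0) * 1e-6    # nm^2/s -> um^2/s
  resid <- sqrt(mean((v - 2 * D * 1e6 * n * dt)^2))
  list(D = D, method = "msd", residual = resid)
}

## Exact Gaussian state-space log-likelihood of one observed axis under
## x_{t+1} = x_t + w (var q), r_t = x_t + v (var R), with a diffuse initial
## state: the first innovation is discarded (translation-invariant
## likelihood, equivalent to the MA(1) displacement likelihood).
kalmanDiffuseLogLik <- function(r, q, R) {
  N <- length(r)
  m <- r[1]
  Pv <- R
  ll <- 0
  for (t in 2:N) {
    Pp <- Pv + q
    S <- Pp + R
    innov <- r[t] - m
    ll <- ll - 0.5 * (log(2 * pi * S) + innov^2 / S)
    K <- Pp / S
    m <- m + K * innov
    Pv <- Pp * (1 - K)
  }
  ll
}

#' Maximum-likelihood diffusion and observation-noise estimation
#'
#' Treats localized positions as noisy linear observations of a hidden
#' random walk: per axis, \eqn{X_{t+1} = X_t + w_t} with
#' \eqn{\mathrm{var}(w) = 2 D \Delta t} and \eqn{r_t = X_t + v_t} with
#' \eqn{\mathrm{var}(v) = R}. The exact Gaussian likelihood is evaluated by a
#' Kalman recursion with a diffuse initial state and maximized over
#' \eqn{(D \ge 0, R \ge 0)} by bounded quasi-Newton from multiple starts
#' (the MSD estimate of D paired with R = 0 and with a localization-scale R).
#'
#' @param positions N x 2 matrix of localized positions (nm), N >= 3
#' @param dt frame interval (s)
#' @return list with `D` (length-2, um^2/s), `obsVar` (length-2, nm^2),
#'   `logLik` (length-2), `method = "mle"`, `degenerate` flag
#' @export
mleDiffusion <- function(positions, dt) {
  positions <- rbind(positions)
  N <- nrow(positions)
  if (N < 3) stop("at least three positions are required")
  fitAxis <- function(r) {
    if (all(r == r[1]))
      return(list(D = 0, R = 0, ll = Inf, degenerate = TRUE))
    msd <- fitMsd(msdCurve(r), dt)
    D0 <- max(msd$D, 1e-8)
    nll <- function(p) -kalmanDiffuseLogLik(r, 2 * p[1] * 1e6 * dt, p[2])
    starts <- list(c(D0, 1e-12), c(D0, 100))  # R = 0 and ~ (10 nm)^2
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        optim(s, nll, method = "L-BFGS-B", lower = c(1e-12, 0),
              upper = c(Inf, Inf),
              control = list(maxit = 500L, factr = 1e4,
                             parscale = c(max(D0, 1e-6), 50))),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    # polish from the winning start (guards against scale-induced stalls)
    o2 <- tryCatch(
      optim(best$par, nll, method = "L-BFGS-B", lower = c(1e-12, 0),
            upper = c(Inf, Inf),
            control = list(maxit = 500L, factr = 1e4,
                           parscale = pmax(best$par, c(1e-6, 1)))),
      error = function(e) NULL)
    if (!is.null(o2) && o2$value < best$value) best <- o2
    list(D = best$par[1], R = best$par[2], ll = -best$value,
         degenerate = FALSE)
  }
  fx <- fitAxis(positions[, 1])
  fy <- fitAxis(positions[, 2])
  list(D = c(fx$D, fy$D), obsVar = c(fx$R, fy$R), logLik = c(fx$ll, fy$ll),
       method = "mle", degenerate = fx$degenerate || fy$degenerate)
}
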