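# Independent oracles used across the suite. These deliberately avoid the
# package's recursions: linear-Gaussian smoothing is done by brute-force
# conditioning of the joint Gaussian, so any Kalman/RTS/FFBS code in the
# package is checked against plain multivariate-normal algebra.

# Joint-Gaussian smoother for one axis of the random-walk tracking model:
#   x_0 ~ N(m0, P0), x_t = x_{t-1} + w (var q), y_t = x_t + v (var R).
# Returns smoothed means/vars for x_0..x_N, lag-one covariances
# cov(x_t, x_{t-1} | y), and the log-likelihood of y.
bruteSmooth1d <- function(y, q, R, m0, P0) {
  N <- length(y)
  n <- N + 1
  idx <- 0:N
  Sigma <- P0 + q * outer(idx, idx, pmin)         # prior cov of x_0..x_N
  mu <- rep(m0, n)
  H <- cbind(matrix(0, N, 1), diag(N))            # y picks x_1..x_N
  Sy <- H %*% Sigma %*% t(H) + diag(R, N)
  Sxy <- Sigma %*% t(H)
  K <- Sxy %*% solve(Sy)
  mPost <- mu + as.vector(K %*% (y - mu[-1]))
  SPost <- Sigma - K %*% t(Sxy)
  ll <- -0.5 * (N * log(2 * pi) + determinant(Sy)$modulus[1] +
                  sum((y - mu[-1]) * solve(Sy, y - mu[-1])))
  list(mean = mPost, var = diag(SPost),
       lag1 = SPost[cbind(2:n, 1:N)], cov = SPost, logLik = ll)
}

# Simulate one axis of the linear-Gaussian model (positions + noisy obs)
simLinear1d <- function(N, q, R, m0 = 0, P0 = 1) {
  x <- numeric(N + 1)
  x[1] <- rnorm(1, m0, sqrt(P0))
  for (t in 1:N) x[t + 1] <- x[t] + rnorm(1, 0, sqrt(q))
  list(x = x, y = x[-1] + rnorm(N, 0, sqrt(R)))
}

# Batched linear observation function for UKF injection: observes the state
# directly in an m = 2 dimensional observation (identity map).
linearObsFun <- function(states, t) t(rbind(states))

# Small scene used when full Table-1 size is not needed
tinyConfig <- function(...) {
  sceneConfig(P = 9L, nFrames = 12L, nSub = 1L, shutter = 0.01,
              G = 200, Nbgd = 5, ...)
}

tableConfig <- function(...) sceneConfig(...)

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
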