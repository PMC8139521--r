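## helper: posterior object from plain summaries (x and y identical)
postFrom <- function(means, vars = 0 * means, lag1 = NULL, initial = TRUE) {
  n <- length(means)
  if (is.null(lag1)) lag1 <- rep(0, n - 1)
  if (initial) {
    m <- cbind(means[-1], means[-1])
    cv <- array(0, c(n - 1, 2, 2))
    cv[, 1, 1] <- vars[-1]; cv[, 2, 2] <- vars[-1]
    lg <- array(0, c(n - 1, 2, 2))
    lg[, 1, 1] <- lag1; lg[, 2, 2] <- lag1
    posteriorTrajectory(m, cv, lg,
                        initial = list(mean = rep(means[1], 2),
                                       cov = diag(vars[1], 2)))
  } else {
    m <- cbind(means, means)
    cv <- array(0, c(n, 2, 2))
    cv[, 1, 1] <- vars; cv[, 2, 2] <- vars
    lg <- array(0, c(n - 1, 2, 2))
    lg[, 1, 1] <- lag1; lg[, 2, 2] <- lag1
    posteriorTrajectory(m, cv, lg)
  }
}

test_that("M-step closed form on hand-worked posteriors", {
  # zero covariances, positions 0, 1, 3 nm over two increments, dt = 1 s:
  # sum of squared increments 5 nm^2 -> D = 5 / (2 * 2 * 1) nm^2/s
  p <- postFrom(c(0, 1, 3))
  D <- mStepDiffusion(p, dt = 1)
  expect_equal(unname(D), rep(1.25e-6, 2), tolerance = 1e-12)  # um^2/s

  # zero displacements, constant variance Pv, zero lag-one -> D = Pv / dt
  Pv <- 7
  p <- postFrom(rep(2, 6), vars = rep(Pv, 6))
  D <- mStepDiffusion(p, dt = 0.5)
  expect_equal(unname(D), rep(2 * Pv / (2 * 0.5) * 1e-6, 2),
               tolerance = 1e-12)
})

test_that("M-step equals numerical maximization of the increment likelihood", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 8
    means <- cumsum(rnorm(n, 0, 20))
    vars <- runif(n, 1, 30)
    # lag-one covariances bounded to keep the joint PSD
    lag1 <- runif(n - 1, 0, 0.5) * sqrt(vars[-1] * vars[-n])
    p <- postFrom(means, vars, lag1)
    dt <- 0.1
    D <- mStepDiffusion(p, dt)[[1]]
    # expected complete-data log-likelihood of the increments in D (nm^2/s)
    eSq <- sum(diff(means)^2 + vars[-1] + vars[-n] - 2 * lag1)
    nInc <- n - 1
    negI2 <- function(Dum) {
      q <- 2 * Dum * 1e6 * dt
      0.5 * (nInc * log(q) + eSq / q)
    }
    opt <- optimize(negI2, c(D / 50, D * 50), tol = 1e-14)
    expect_equal(D, opt$minimum, tolerance = 1e-7)
  }
})

test_that("M-step is invariant to translation of the posterior means", {
  set.seed(32)
  means <- cumsum(rnorm(7, 0, 15))
  p1 <- postFrom(means, vars = rep(4, 7))
  p2 <- postFrom(means + 1e4, vars = rep(4, 7))
  expect_equal(mStepDiffusion(p1, 0.1), mStepDiffusion(p2, 0.1),
               tolerance = 1e-10)
})

test_that("linear-model EM converges to the direct Kalman MLE", {
  dt <- 0.1
  set.seed(33)
  q <- 2 * 0.005e6 * dt
  R <- 45
  sim <- simLinear1d(1000, q, R, m0 = 0, P0 = 100)
  sim2 <- simLinear1d(1000, 2 * q, R, m0 = 0, P0 = 100)
  y <- cbind(sim$y, sim2$y)
  prior <- list(mean = c(0, 0), cov = diag(100, 2))
  em <- runEM(y, kalmanBackend(c(R, R)), theta0 = c(0.002, 0.02),
              maxIter = 60L, tol = 1e-8, prior = prior, dt = dt)
  # oracle: direct likelihood maximization with R known
  dir <- sapply(1:2, function(a) {
    optimize(function(D) -sptEM:::kalmanDiffuseLogLik(y[, a], 2 * D * 1e6 * dt,
                                                      R),
             c(1e-4, 0.1), tol = 1e-12)$minimum
  })
  # EM (prior fixed, R known) and the diffuse MLE agree within a few SE;
  # SE of D-hat ~ D * sqrt(2/N)
  se <- dir * sqrt(2 / 1000)
  expect_true(all(abs(as.numeric(finalTheta(em)) - dir) < 3 * se))
})

test_that("EM is stationary at its own fixed point and respects maxIter", {
  dt <- 0.1
  set.seed(34)
  sim <- simLinear1d(200, 1000, 45)
  y <- cbind(sim$y, sim$y)
  prior <- list(mean = y[1, ], cov = diag(100, 2))
  be <- kalmanBackend(c(45, 45))
  em1 <- runEM(y, be, theta0 = c(0.004, 0.004), maxIter = 40L, tol = 1e-10,
               prior = prior, dt = dt)
  fix <- as.numeric(finalTheta(em1))
  em2 <- runEM(y, be, theta0 = fix, maxIter = 1L, tol = 0, prior = prior,
               dt = dt)
  expect_equal(as.numeric(finalTheta(em2)), fix, tolerance = 1e-4)
  em3 <- runEM(y, be, theta0 = c(0.004, 0.004), maxIter = 3L, tol = 0,
               prior = prior, dt = dt)
  expect_equal(em3@iterations, 3L)
  expect_equal(nrow(thetaTrace(em3)), 4L)   # initial value + 3 updates
})

test_that("exact-Kalman EM has a non-decreasing data log-likelihood", {
  dt <- 0.1
  set.seed(35)
  sim <- simLinear1d(300, 800, 60)
  sim2 <- simLinear1d(300, 1600, 60)
  y <- cbind(sim$y, sim2$y)
  prior <- list(mean = c(0, 0), cov = diag(200, 2))
  em <- runEM(y, kalmanBackend(c(60, 60)), theta0 = c(0.0005, 0.03),
              maxIter = 15L, tol = 0, prior = prior, dt = dt)
  tt <- thetaTrace(em)
  ll <- apply(tt, 1, function(th)
    linearGaussianLogLik(y, th, c(60, 60), prior, dt))
  expect_true(all(diff(ll) >= -1e-10 * abs(ll[-1])))
})

test_that("EM aborts with a failure flag when the backend diverges", {
  failingBackend <- structure(list(
    tag = "failing",
    smooth = function(obs, theta, prior, config = NULL, maps = NULL, dt)
      list(posterior = NULL, ok = FALSE)), class = "sptemBackend")
  y <- cbind(rnorm(10), rnorm(10))
  em <- runEM(y, failingBackend, theta0 = c(0.01, 0.01), prior =
                list(mean = c(0, 0), cov = diag(1, 2)), dt = 0.1)
  expect_true(emFailed(em))
  expect_equal(em@iterations, 0L)
})
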