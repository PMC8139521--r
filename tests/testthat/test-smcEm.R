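## dummy stack carrying only the shape and timing for injected-likelihood runs
dummyStack <- function(N, dt = 0.1) {
  cfg <- sceneConfig(P = 3L, nFrames = N, nSub = 1L, dt = dt, G = 0, Nbgd = 1)
  frameStack(array(0, c(N, 3, 3)), cfg)
}

test_that("pixel log-likelihood matches direct Poisson arithmetic", {
  # single effective pixel: 1x1 grid... use a tiny frame and sum by hand
  cfg <- sceneConfig(P = 3L, nFrames = 1L, nSub = 1L, G = 40, Nbgd = 2)
  fr <- matrix(c(3, 0, 1, 2, 5, 0, 0, 1, 2), 3, 3)
  st <- c(150, 150)
  lam <- expectedPixelRates(st, cfg)
  manual <- sum(dpois(fr, lam + 2, log = TRUE))
  expect_equal(pixelLogLikelihood(fr, st, cfg), manual, tolerance = 1e-10)

  # batched version agrees with the reference routine on random frames
  cfg2 <- tinyConfig()
  set.seed(51)
  for (rep in 1:3) {
    f <- renderFrame(expectedPixelRates(c(450, 450), cfg2), cfg2)
    states <- cbind(runif(5, 100, 800), runif(5, 100, 800))
    ll <- pixelLogLikelihood(f, states, cfg2)
    ref <- apply(states, 1, function(s)
      sum(dpois(f, expectedPixelRates(s, cfg2) + cfg2@Nbgd, log = TRUE)))
    expect_close(ll, ref, 1e-9)
  }

  # single pixel, I = 3 at rate 2: 3 log 2 - 2 - log 6
  cfg1 <- sceneConfig(P = 3L, nFrames = 1L, nSub = 1L, G = 0, Nbgd = 2)
  f0 <- matrix(0, 3, 3); f0[1, 1] <- 3
  ll <- pixelLogLikelihood(f0, c(150, 150), cfg1)
  expect_equal(ll, 3 * log(2) - 2 - log(6) + 8 * (-2), tolerance = 1e-10)
})

test_that("sCMOS batch likelihood matches the per-pixel density", {
  cfg <- sceneConfig(P = 7L, nFrames = 1L, nSub = 1L, G = 30, Nbgd = 4,
                     cameraKind = "scmos")
  set.seed(52)
  maps <- makeScmosMaps(7)
  f <- renderFrame(expectedPixelRates(c(350, 350), cfg), cfg, maps)
  states <- cbind(runif(4, 150, 550), runif(4, 150, 550))
  ll <- pixelLogLikelihood(f, states, cfg, maps)
  rv <- readoutVariance(maps); g <- gainMap(maps)
  ref <- apply(states, 1, function(s) {
    lam <- expectedPixelRates(s, cfg)
    sum(log(mapply(function(v, l, vv, gg)
      scmosPixelDensity(v, l, cfg@Nbgd, vv, gg), f, lam, rv, g)))
  })
  expect_close(ll, ref, 2e-4)
})

test_that("likelihood prefers the true position over a distant one", {
  cfg <- tableConfig()
  set.seed(53)
  wins <- replicate(60, {
    pos <- c(1250, 1250) + runif(2, -200, 200)
    f <- renderFrame(expectedPixelRates(pos, cfg), cfg)
    far <- pos + c(500, 0)
    diff(pixelLogLikelihood(f, rbind(pos, far), cfg)) < 0
  })
  expect_gte(mean(wins), 0.99)
})

test_that("particle filter matches the exact Kalman filter on linear obs", {
  dt <- 0.1
  N <- 25
  q <- 900; R <- 50
  set.seed(54)
  s1 <- simLinear1d(N, q, R); s2 <- simLinear1d(N, q, R)
  y <- cbind(s1$y, s2$y)
  loglik <- function(t, states)
    dnorm(y[t, 1], states[, 1], sqrt(R), log = TRUE) +
      dnorm(y[t, 2], states[, 2], sqrt(R), log = TRUE)
  prior <- list(mean = c(0, 0), cov = diag(100, 2))
  D <- q / (2 * dt) * 1e-6
  pf <- particleFilter(dummyStack(N, dt), c(D, D), 5000, prior,
                       logLikFun = loglik)
  expect_true(pf$ok)
  br <- bruteSmooth1d(y[, 1], q, R, 0, 100)
  # filtered mean at every frame within 3 MC standard errors of exact value
  for (t in c(3, 10, 17, 25)) {
    wm <- sum(pf$w[, t + 1] * pf$xs[, t + 1])
    wv <- sum(pf$w[, t + 1] * (pf$xs[, t + 1] - wm)^2)
    ess <- 1 / sum(pf$w[, t + 1]^2)
    # exact filtered mean from a brute conditioning on y_1..y_t
    brt <- bruteSmooth1d(y[1:t, 1], q, R, 0, 100)
    expect_lt(abs(wm - brt$mean[t + 1]), 3.5 * sqrt(wv / ess) + 1e-9)
  }

  # FFBS smoothed moments vs brute-force joint conditioning
  ps <- particleSmoother(pf)
  mcse <- sqrt(smoothedCov(ps)[, 1, 1] / 400)   # conservative MC scale
  expect_true(all(abs(smoothedMean(ps)[, 1] - br$mean[-1]) <
                    4 * mcse + 2))
  # smoothed variances within 25% of the exact ones on average
  relv <- smoothedCov(ps)[, 1, 1] / br$var[-1]
  expect_lt(abs(mean(relv) - 1), 0.25)
  # lag-one covariances track the exact values
  rell <- mean(lagOneCov(ps)[, 1, 1]) / mean(br$lag1)
  expect_lt(abs(rell - 1), 0.3)
  # boundary: smoothed weights equal filtered weights at the last frame
  wS <- attr(ps, "weights")
  expect_equal(wS[, N + 1], pf$w[, N + 1], tolerance = 1e-12)
})

test_that("smoothing reduces the position variance on average", {
  dt <- 0.1
  N <- 30
  q <- 600; R <- 40
  set.seed(55)
  s1 <- simLinear1d(N, q, R); s2 <- simLinear1d(N, q, R)
  y <- cbind(s1$y, s2$y)
  loglik <- function(t, states)
    dnorm(y[t, 1], states[, 1], sqrt(R), log = TRUE) +
      dnorm(y[t, 2], states[, 2], sqrt(R), log = TRUE)
  D <- q / (2 * dt) * 1e-6
  pf <- particleFilter(dummyStack(N, dt), c(D, D), 2000,
                       list(mean = c(0, 0), cov = diag(100, 2)),
                       logLikFun = loglik)
  ps <- particleSmoother(pf)
  fVar <- sapply(1:N, function(t) {
    wm <- sum(pf$w[, t + 1] * pf$xs[, t + 1])
    sum(pf$w[, t + 1] * (pf$xs[, t + 1] - wm)^2)
  })
  expect_lt(mean(smoothedCov(ps)[, 1, 1]), mean(fVar) * 1.02)
})

test_that("degenerate dynamics and reproducibility contracts", {
  # D = 0 with a point-mass prior: all particles identical forever
  N <- 5
  st <- dummyStack(N)
  pf <- particleFilter(st, c(0, 0), 50,
                       list(mean = c(7, 9), cov = diag(1e-12, 2)),
                       logLikFun = function(t, s) rep(0, nrow(s)))
  expect_true(all(abs(pf$xs - 7) < 1e-3) && all(abs(pf$ys - 9) < 1e-3))

  # fixed seed -> bit-identical clouds
  cfg <- tinyConfig()
  set.seed(56)
  tr <- simulateTrajectory(cfg)
  stk <- renderStack(tr, cfg)
  prior <- list(mean = c(450, 450), cov = diag(100^2, 2))
  set.seed(57)
  p1 <- particleFilter(stk, c(0.005, 0.005), 100, prior)
  set.seed(57)
  p2 <- particleFilter(stk, c(0.005, 0.005), 100, prior)
  expect_identical(p1$xs, p2$xs)
  expect_identical(p1$w, p2$w)
  expect_error(particleFilter(stk, c(0.005, 0.005), 1, prior), ">= 2")
})

test_that("SMC-EM on the image model agrees with the linear-model EM target", {
  # full image pipeline at an easy setting recovers D within Monte Carlo error
  cfg <- sceneConfig(nFrames = 60L)
  set.seed(58)
  tr <- simulateTrajectory(cfg)
  stk <- renderStack(tr, cfg)
  set.seed(59)
  em <- runEM(stk, smcEmBackend(300))
  expect_false(emFailed(em))
  D <- as.numeric(finalTheta(em))
  expect_gt(D[1], 0.001); expect_lt(D[1], 0.02)
  expect_gt(D[2], 0.002); expect_lt(D[2], 0.04)
})
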