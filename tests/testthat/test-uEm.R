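test_that("Anscombe transform values and variance stabilization", {
  cfg <- sceneConfig(P = 3L, nFrames = 1L, nSub = 1L, G = 0, Nbgd = 0)
  st <- frameStack(array(0, c(1, 3, 3)), cfg)
  expect_equal(anscombeTransform(st)[1, 1, 1], 2 * sqrt(3 / 8),
               tolerance = 1e-12)
  st10 <- frameStack(array(10, c(1, 3, 3)), cfg)
  maps1 <- cameraMaps(matrix(1, 3, 3))
  expect_equal(anscombeTransform(st10, maps1)[1, 1, 1], 2 * sqrt(11.375),
               tolerance = 1e-12)
  # variance stabilization at lambda = 20
  set.seed(41)
  v <- var(2 * sqrt(rpois(1e5, 20) + 3 / 8))
  expect_gt(v, 0.9); expect_lt(v, 1.1)
})

test_that("transformed observation function is definitionally consistent", {
  cfg <- tinyConfig()
  # G = 0 -> constant vector
  cfg0 <- sceneConfig(P = 5L, nFrames = 1L, nSub = 1L, G = 0, Nbgd = 6)
  h0 <- ukfTransformedObservation(c(250, 250), cfg0)
  expect_true(all(abs(h0 - 2 * sqrt(6 + 3 / 8)) < 1e-12))
  # matches the Anscombe transform of the noiseless rate map + background
  pos <- c(430, 470)
  lam <- expectedPixelRates(pos, cfg)
  expect_equal(ukfTransformedObservation(pos, cfg),
               as.vector(2 * sqrt(lam + cfg@Nbgd + 3 / 8)), tolerance = 1e-12)
  # mirror symmetry on a 5 x 5 grid: reflected states give reflected vectors
  cfg5 <- sceneConfig(P = 5L, nFrames = 1L, nSub = 1L)
  hA <- matrix(ukfTransformedObservation(c(150, 250), cfg5), 5, 5)
  hB <- matrix(ukfTransformedObservation(c(350, 250), cfg5), 5, 5)
  expect_equal(hA, hB[, 5:1], tolerance = 1e-10)
})

test_that("UKF equals the exact Kalman filter on a linear model", {
  dt <- 0.1
  set.seed(42)
  q <- 2 * 0.003e6 * dt
  R <- 50
  s1 <- simLinear1d(40, q, R); s2 <- simLinear1d(40, 2 * q, R)
  y <- cbind(s1$y, s2$y)
  prior <- list(mean = c(10, -5), cov = diag(c(400, 900)))
  flt <- ukfFilter(y, c(0.003, 0.006), dt, prior, linearObsFun, Rdiag = R)
  expect_true(flt$ok)
  # exact joint-Gaussian oracle, axis by axis
  for (a in 1:2) {
    br <- bruteSmooth1d(y[, a], q * a, R, prior$mean[a],
                        diag(prior$cov)[a])
    # filtered mean at the last step equals the smoothed mean at the end
    expect_equal(flt$mf[41, a], br$mean[41], tolerance = 1e-8)
  }
  # full smoothed trajectory (URTSS) vs brute-force conditioning
  ps <- urtssSmooth(flt)
  for (a in 1:2) {
    br <- bruteSmooth1d(y[, a], q * a, R, prior$mean[a], diag(prior$cov)[a])
    expect_close(smoothedMean(ps)[, a], br$mean[-1], 1e-7)
    expect_close(smoothedCov(ps)[, a, a], br$var[-1], 1e-7)
    expect_close(lagOneCov(ps)[, a, a], br$lag1, 1e-7)
    init <- initialState(ps)
    expect_equal(init$mean[a], br$mean[1], tolerance = 1e-8)
    expect_equal(init$cov[a, a], br$var[1], tolerance = 1e-7)
  }
})

test_that("URTSS boundary condition and variance reduction", {
  dt <- 0.1
  set.seed(43)
  s1 <- simLinear1d(30, 700, 40); s2 <- simLinear1d(30, 900, 40)
  y <- cbind(s1$y, s2$y)
  prior <- list(mean = c(0, 0), cov = diag(300, 2))
  flt <- ukfFilter(y, c(0.0035, 0.0045), dt, prior, linearObsFun, Rdiag = 40)
  ps <- urtssSmooth(flt)
  # last smoothed state equals last filtered state
  expect_equal(smoothedMean(ps)[30, ], flt$mf[31, ], tolerance = 1e-10)
  expect_equal(smoothedCov(ps)[30, , ], flt$Pf[31, , ], tolerance = 1e-10)
  # smoothed covariances are below filtered ones in the Loewner order
  for (t in 1:30) {
    d <- flt$Pf[t + 1, , ] - smoothedCov(ps)[t, , ]
    expect_gte(min(eigen(d, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("filtered covariance shrinks with repeated identical information", {
  # zero process noise and a fixed informative frame: uncertainty can only
  # decrease as evidence accumulates
  cfg <- tinyConfig()
  set.seed(44)
  lam <- expectedPixelRates(c(430, 470), cfg)
  f <- renderFrame(lam, cfg)
  y <- matrix(rep(2 * sqrt(as.vector(f) + 3 / 8), 6), nrow = 6, byrow = TRUE)
  h <- sptEM:::pixelObsFun(cfg)
  flt <- ukfFilter(y, c(0, 0), cfg@dt, list(mean = c(450, 450),
                                            cov = diag(50^2, 2)), h)
  expect_true(flt$ok)
  vols <- apply(flt$Pf, 1, function(m) det(matrix(m, 2, 2)))
  expect_true(all(diff(vols) <= 1e-8))
})

test_that("sigma-point weights sum to one for admissible settings", {
  for (a in c(0.5, 1, 2)) for (k in c(0.5, 1, 3)) {
    s <- ukfSettings(alpha = a, kappa = k)
    expect_equal(sum(s$wm), 1, tolerance = 1e-12)
  }
})

test_that("U-EM tracks an easy sequence and flags hard failures as such", {
  cfg <- sceneConfig(nFrames = 40L)
  set.seed(45)
  tr <- simulateTrajectory(cfg)
  st <- renderStack(tr, cfg)
  em <- runEM(st, uEmBackend())
  expect_false(emFailed(em))
  r <- rmse(smoothedMean(posteriorOf(em)), truePositions(st))
  expect_lt(r[["x"]], 15)   # coarse sanity bound at high signal
})
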