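test_that("PSF width follows the optics formula and its scalings", {
  s <- psfSigmaFromOptics(540, 1.2)
  expect_equal(unname(s[1]), sqrt(2) * 540 / (2 * pi * 1.2), tolerance = 1e-12)
  expect_equal(unname(s[1]), 101.2856, tolerance = 1e-4)
  expect_equal(s[["sigmaX"]], s[["sigmaY"]])
  expect_equal(psfSigmaFromOptics(1080, 1.2)[[1]], 2 * s[[1]])
  expect_equal(psfSigmaFromOptics(540, 2.4)[[1]], s[[1]] / 2)
  expect_error(psfSigmaFromOptics(-1, 1.2), "positive")
  expect_error(psfSigmaFromOptics(540, 0), "positive")
})

test_that("trajectory simulation: zero diffusion, shapes, increment variance", {
  cfg <- sceneConfig(Dx = 0, Dy = 0)
  set.seed(1)
  tr <- simulateTrajectory(cfg)
  expect_true(all(subPositions(tr)[, 1] == 1250))
  expect_true(all(subPositions(tr)[, 2] == 1250))

  # Table-1 shapes: N = 100 frames, sub-sampling 100
  cfg <- sceneConfig()
  set.seed(2)
  tr <- simulateTrajectory(cfg)
  expect_equal(dim(subPositions(tr)), c(10000L, 2L))
  expect_equal(dim(framePositions(tr)), c(100L, 2L))
  expect_equal(framePositions(tr),
               subPositions(tr)[seq(1, 10000, by = 100), ])

  # sample variance of increments vs chi-square sampling distribution:
  # 1e5 substeps at D = 0.005, dt = 0.1 s, nSub = 100 -> var = 10 nm^2
  cfg <- sceneConfig(nFrames = 1000L, nSub = 100L)
  set.seed(3)
  tr <- simulateTrajectory(cfg)
  inc <- diff(subPositions(tr)[, 1])
  n <- length(inc)
  v <- var(inc)
  se <- 10 * sqrt(2 / (n - 1))          # sd of the sample variance
  expect_lt(abs(v - 10), 3 * se)

  expect_error(sceneConfig(Dx = -1), "Dx")
  expect_error(sceneConfig(dt = 0), "dt")
})

test_that("expected pixel rates match 2-D quadrature of the PSF integral", {
  skip_if_not_installed("pracma")
  cfg <- tinyConfig()
  sx <- cfg@psfSigmaX
  psf <- function(x, y, x0, y0)
    cfg@G * exp(-(x - x0)^2 / (2 * sx^2) - (y - y0)^2 / (2 * sx^2))
  set.seed(4)
  for (rep in 1:5) {
    pos <- runif(2, -100, 1000)   # may lie outside the field
    r <- expectedPixelRates(pos, cfg)
    i <- sample(cfg@P, 1); j <- sample(cfg@P, 1)
    q <- pracma::integral2(function(x, y) psf(x, y, pos[1], pos[2]),
                           (j - 1) * cfg@dx, j * cfg@dx,
                           (i - 1) * cfg@dy, i * cfg@dy,
                           reltol = 1e-13)$Q / (cfg@dx * cfg@dy)
    expect_lt(abs(r[i, j] - q), 1e-10 * cfg@G)
  }
})

test_that("rate map symmetry, mass bound, and narrow-sigma limit", {
  cfg <- tinyConfig()                      # odd grid, P = 9
  ctr <- c(9 * 100 / 2, 9 * 100 / 2)
  r <- expectedPixelRates(ctr, cfg)
  expect_equal(r, r[, 9:1], tolerance = 1e-12)   # horizontal reflection
  expect_equal(r, r[9:1, ], tolerance = 1e-12)   # vertical reflection
  expect_equal(r, t(r), tolerance = 1e-12)       # diagonal reflection
  expect_equal(unname(which.max(r)), 5L + 4L * 9L)  # central pixel
  expect_lte(sum(r), cfg@G * 2 * pi * cfg@psfSigmaX * cfg@psfSigmaY / 1e4)

  # sigma_x << dx: all x-mass falls in the column containing the emitter
  cfgN <- sceneConfig(P = 9L, nFrames = 2L, nSub = 1L, psfSigmaX = 1,
                      psfSigmaY = 120, G = 50)
  rn <- expectedPixelRates(c(450, 450), cfgN)
  colMass <- colSums(rn)
  expect_equal(sum(colMass[-5]), 0, tolerance = 1e-12)
  yFactor <- sqrt(2 * pi) * 120 / 100 *
    sum(diff(pnorm(((0:9) * 100 - 450) / 120)))
  expect_equal(colMass[5], 50 * sqrt(2 * pi) * 1 / 100 * yFactor,
               tolerance = 1e-9)
})

test_that("blurred rates average the per-subposition maps", {
  cfg <- tinyConfig()
  p1 <- c(430, 470); p2 <- c(480, 440)
  expect_equal(blurredRates(rbind(p1, p1, p1), cfg),
               expectedPixelRates(p1, cfg), tolerance = 1e-12)
  expect_equal(blurredRates(rbind(p1, p2), cfg),
               (expectedPixelRates(p1, cfg) + expectedPixelRates(p2, cfg)) / 2,
               tolerance = 1e-12)
  expect_error(blurredRates(matrix(0, 0, 2), cfg), "sub-position")
  # Table-1 settings: the shutter spans 10 sub-steps
  expect_equal(sptEM:::nBlurSteps(sceneConfig()), 10L)
})

test_that("ideal camera rendering is Poisson with the background added", {
  cfg <- sceneConfig(G = 0, Nbgd = 7, P = 5L, nFrames = 2L, nSub = 1L)
  rates <- matrix(0, 5, 5)
  set.seed(5)
  draws <- replicate(4000, renderFrame(rates, cfg)[2, 3])
  n <- length(draws)
  expect_lt(abs(mean(draws) - 7), 3 * sqrt(7 / n))
  expect_lt(abs(var(draws) - 7), 3 * 7 * sqrt(2 / (n - 1)))

  # chi-square goodness of fit against Poisson(7) at alpha = 0.01
  brk <- c(-0.5, seq(1.5, 13.5, by = 1), Inf)
  obs <- table(cut(draws, brk))
  pr <- diff(c(0, ppois(c(1, 2:13), 7), 1))
  chi <- sum((obs - n * pr)^2 / (n * pr))
  expect_lt(chi, qchisq(0.99, length(pr) - 1))

  # Table-1 frame dimensions
  set.seed(6)
  tr <- simulateTrajectory(sceneConfig())
  st <- renderStack(tr, sceneConfig())
  expect_equal(dim(frames(st)), c(100L, 25L, 25L))
})

test_that("sCMOS rendering adds pixel-wise Gaussian readout variance", {
  cfg <- sceneConfig(G = 0, Nbgd = 10, P = 3L, nFrames = 2L, nSub = 1L,
                     cameraKind = "scmos")
  maps <- cameraMaps(matrix(4, 3, 3))    # unit gain
  set.seed(7)
  draws <- replicate(4000, renderFrame(matrix(0, 3, 3), cfg, maps)[1, 1])
  n <- length(draws)
  expect_lt(abs(var(draws) - 14), 3 * 14 * sqrt(2 / (n - 1)) * 1.3)
  expect_error(renderFrame(matrix(0, 3, 3), cfg), "maps")
})

test_that("sCMOS pixel density normalizes, has the Poisson mean, and limits", {
  dens <- function(v) scmosPixelDensity(v, 12, 3, 2.5)
  total <- integrate(dens, -50, 15 + 50 * (1 + sqrt(2.5)),
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  expect_lt(abs(total - 1), 1e-6)
  m <- integrate(function(v) v * dens(v), -60, 120, rel.tol = 1e-10)$value
  expect_lt(abs(m - 15), 1e-6)
  # empty Poisson component: density is the centred Gaussian
  v <- seq(-5, 5, by = 0.5)
  expect_equal(scmosPixelDensity(v, 0, 0, 2), dnorm(v, 0, sqrt(2)),
               tolerance = 1e-12)
  expect_error(scmosPixelDensity(1, 1, 1, 0), "positive")
})

test_that("synthetic sCMOS maps are reproducible with documented moments", {
  set.seed(11)
  m1 <- makeScmosMaps(25)
  set.seed(11)
  m2 <- makeScmosMaps(25)
  expect_identical(readoutVariance(m1), readoutVariance(m2))
  expect_identical(gainMap(m1), gainMap(m2))
  expect_true(all(readoutVariance(m1) > 0) && all(gainMap(m1) >= 0.5))

  # degenerate spec -> constant maps
  set.seed(12)
  md <- makeScmosMaps(5, varMedian = 3, varLogSd = 0, gainMean = 1,
                      gainSd = 0)
  expect_equal(max(abs(readoutVariance(md) - 3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gainMap(md) - 1)), 0, tolerance = 1e-12)

  # log-normal mean = median * exp(sd^2/2); check within 3 SE over 625 px
  set.seed(13)
  mv <- readoutVariance(makeScmosMaps(25))
  mTheo <- 2 * exp(0.6^2 / 2)
  sdTheo <- mTheo * sqrt(exp(0.6^2) - 1)
  expect_lt(abs(mean(mv) - mTheo), 3 * sdTheo / 25)
  expect_error(makeScmosMaps(5, varMedian = -1), "positive")
})

test_that("dataset generation is a pure function of (config, seed)", {
  cfg <- tinyConfig()
  d1 <- generateDataset(cfg, 2, 42)
  d2 <- generateDataset(cfg, 2, 42)
  expect_identical(frames(d1[[1]]$stack), frames(d2[[1]]$stack))
  expect_identical(subPositions(d1[[2]]$trajectory),
                   subPositions(d2[[2]]$trajectory))
  expect_false(identical(frames(d1[[1]]$stack), frames(d1[[2]]$stack)))
})

test_that("frame-to-frame displacement covariance matches 2 D dt", {
  cfg <- sceneConfig(nFrames = 4000L, nSub = 1L)
  set.seed(14)
  tr <- simulateTrajectory(cfg)
  d <- diff(framePositions(tr))
  n <- nrow(d)
  vx <- 2 * 0.005e6 * 0.1          # 1000 nm^2
  vy <- 2 * 0.01e6 * 0.1
  expect_lt(abs(var(d[, 1]) - vx), 3 * vx * sqrt(2 / (n - 1)))
  expect_lt(abs(var(d[, 2]) - vy), 3 * vy * sqrt(2 / (n - 1)))
  expect_lt(abs(cor(d[, 1], d[, 2])), 3 / sqrt(n))
})

test_that("tracked segmentation keeps the particle near the window centre", {
  cfg <- sceneConfig(Dx = 1, Dy = 1, nFrames = 50L, nSub = 1L)
  set.seed(15)
  tr <- simulateTrajectory(cfg)
  st <- renderStack(tr, cfg)
  rel <- truePositions(st) - windowOrigins(st)
  ctr <- c(1250, 1250)
  expect_true(all(abs(rel[, 1] - ctr[1]) < 5 * cfg@dx))
  expect_true(all(windowOrigins(st) %% cfg@dx == 0))
})
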