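test_that("well-tempered deposition heights follow the tempering rule", {
  p <- metadParams(temperature = 300)
  b <- BiasPotential(sigma = p$sigma, gamma = p$gamma, temperature = 300)
  b1 <- depositGaussian(b, 0, p)
  expect_equal(b1@heights, 3.0)           # first deposition at full height
  # a revisited centre where V = kB*DeltaT*ln(2) deposits at half height
  deltaT <- (p$gamma - 1) * 300
  target <- 0.008314462618 * deltaT * log(2)
  bManual <- initialize(b1, centers = c(0, 0),
                        heights = c(3, target - 3),
                        times = c(NA_real_, NA_real_))
  b2 <- depositGaussian(bManual, 0, p)
  expect_equal(tail(b2@heights, 1), 1.5, tolerance = 1e-9)
  # gamma -> Inf: standard metadynamics, constant height
  pInf <- metadParams(gamma = Inf, temperature = 300)
  b3 <- depositGaussian(b2, 0, pInf)
  expect_equal(tail(b3@heights, 1), 3.0)
  expect_error(metadParams(gamma = 1), "exceed 1")
})

test_that("bias evaluation is consistent between direct and gridded paths", {
  set.seed(8)
  b <- BiasPotential(sigma = 0.02, gamma = 8, temperature = 300)
  b <- initialize(b, centers = runif(300, -1, 1),
                  heights = runif(300, 0.5, 3),
                  times = seq_len(300))
  sFew <- seq(-1, 1, length.out = 100)        # direct path
  sMany <- seq(-1, 1, length.out = 2000)      # gridded path
  direct <- vapply(sMany, function(si) {
    d <- si - b@centers
    sel <- abs(d) <= 6 * 0.02
    sum(b@heights[sel] * exp(-d[sel]^2 / (2 * 0.02^2)))
  }, numeric(1))
  expect_equal(evaluateBias(b, sMany), direct, tolerance = 1e-3)
  expect_equal(evaluateBias(b, sFew),
               evaluateBias(b, sFew, tmax = Inf), tolerance = 1e-12)
})

test_that("geometric ladders hit the endpoints with constant ratio", {
  expect_equal(ladderTemperatures(buildLadder(300, 450, 2)), c(300, 450))
  expect_equal(ladderTemperatures(buildLadder(300, 450, 3))[2],
               sqrt(300 * 450), tolerance = 1e-10)
  t79 <- ladderTemperatures(buildLadder(300, 450, 79))
  expect_length(t79, 79L)
  expect_true(all(diff(t79) > 0))
  expect_lt(diff(range(t79[-1] / t79[-79])), 1e-12)
  expect_error(buildLadder(300, 450, 1), "2 replicas")
  expect_error(buildLadder(450, 300, 5), "below")
})

test_that("metadynamics flattens a flat potential and respects pace", {
  flat <- toyPotential("flat-1d", lo = -1, hi = 1, kwall = 500)
  run <- runMetadynamics(flat, metadParams(temperature = 300),
                         nSteps = 5e5, seed = 3, recordStride = 10)
  x <- cvValues(run$trajectory)
  x <- x[seq(length(x) / 2, length(x))]
  h <- hist(x[x > -0.9 & x < 0.9], breaks = seq(-0.9, 0.9, length.out = 10),
            plot = FALSE)
  expect_lt(diff(range(h$counts)) / mean(h$counts), 0.4)
  # fewer steps than the pace: no depositions
  none <- runMetadynamics(flat, metadParams(pace = 1000, temperature = 300),
                          nSteps = 500, seed = 1)
  expect_length(none$bias@centers, 0L)
  # determinism
  a <- runMetadynamics(flat, metadParams(temperature = 300), nSteps = 2e4,
                       seed = 5)
  b <- runMetadynamics(flat, metadParams(temperature = 300), nSteps = 2e4,
                       seed = 5)
  expect_identical(trajectoryData(a$trajectory), trajectoryData(b$trajectory))
  expect_identical(a$bias@heights, b$bias@heights)
})

test_that("the FES estimator inverts the converged bias", {
  b <- BiasPotential(sigma = 0.05, gamma = 8, temperature = 300)
  empty <- suppressWarnings(fesFromBias(b, -1, 1, 50))
  expect_true(all(fesValues(empty) == 0))
  expect_warning(fesFromBias(b, -1, 1, 50), "empty bias")
  # single Gaussian: F drops by gamma/(gamma-1) * h at the centre
  b1 <- initialize(b, centers = 0, heights = 2, times = 1)
  f <- fesFromBias(b1, -1, 1, 401)
  v <- fesValues(f) * kBT(300)     # back to kJ/mol
  ctr <- which.min(abs(fesAxes(f)[[1]]$centers))
  expect_equal(v[length(v)] - v[ctr], (8 / 7) * 2, tolerance = 1e-3)
  # planted double well: argmin of the estimated FES is the deeper well
  dw <- makeDoubleWell(deltaF_kT = 3, barrier = 8, temperature = 300)
  run <- runMetadynamics(dw$potential, metadParams(temperature = 300),
                         nSteps = 1e6, seed = 11, friction = 50,
                         recordStride = 100)
  fdw <- fesFromBias(run$bias, -0.5, 0.5, 200)
  xmin <- fesAxes(fdw)[[1]]$centers[which.min(fesValues(fdw))]
  expect_gt(xmin, 0.075)   # deeper well planted at x = +0.15
})

test_that("well-tempered heights decay on revisited regions", {
  dw <- makeDoubleWell(deltaF_kT = 1, barrier = 5, temperature = 300)
  run <- runMetadynamics(dw$potential, metadParams(temperature = 300),
                         nSteps = 1e6, seed = 2, friction = 50,
                         recordStride = 100)
  h <- run$bias@heights
  n <- length(h)
  expect_lt(mean(tail(h, n %/% 4)), mean(head(h, n %/% 4)))
  expect_true(all(h > 0))
})

test_that("exchange acceptance follows the Metropolis rule", {
  # equal temperatures, identical biases: delta = 0, always accepted
  d0 <- attemptExchange(5, 9, 0.1, 0.4, NULL, NULL, 300, 300, u = 0.999999)
  expect_equal(d0$prob, 1)
  expect_true(d0$accept)
  d1 <- attemptExchange(3, 3, 0, 0, NULL, NULL, 300, 400, u = 0.5)
  expect_equal(d1$prob, 1)
  # empirical acceptance vs brute-force Monte-Carlo estimate
  pot <- toyPotential("harmonic", k = 10)
  run <- runPTMetaD(pot, c(300, 400), metadParams(height = 1e-9),
                    nSteps = 4e5, exchangeStride = 1000, seed = 5,
                    recordStride = 10)
  acc <- run$acceptanceRate
  att <- run$ladder@attempts
  set.seed(1)
  n <- 2e5
  xi <- rnorm(n, sd = sqrt(kBT(300) / 10))
  xj <- rnorm(n, sd = sqrt(kBT(400) / 10))
  delta <- (1 / kBT(300) - 1 / kBT(400)) * (5 * xi^2 - 5 * xj^2)
  pRef <- mean(pmin(1, exp(delta)))
  se <- sqrt(pRef * (1 - pRef) / att)
  expect_lt(abs(acc - pRef), 3 * se + 3 * sd(pmin(1, exp(delta))) / sqrt(n))
})

test_that("parallel tempering preserves per-temperature Boltzmann statistics", {
  pot <- toyPotential("harmonic", k = 10)
  run <- runPTMetaD(pot, c(300, 400), metadParams(height = 1e-9),
                    nSteps = 4e5, exchangeStride = 1000, seed = 5,
                    recordStride = 10)
  v300 <- var(cvValues(run$trajectories[[1]]))
  v400 <- var(cvValues(run$trajectories[[2]]))
  expect_lt(abs(v300 / (kBT(300) / 10) - 1), 0.05)
  expect_lt(abs(v400 / (kBT(400) / 10) - 1), 0.05)
  # determinism of the full multi-replica run
  a <- runPTMetaD(pot, c(300, 400), metadParams(), nSteps = 2e4,
                  exchangeStride = 1000, seed = 9, recordStride = 10)
  b <- runPTMetaD(pot, c(300, 400), metadParams(), nSteps = 2e4,
                  exchangeStride = 1000, seed = 9, recordStride = 10)
  for (r in 1:2) {
    expect_identical(trajectoryData(a$trajectories[[r]]),
                     trajectoryData(b$trajectories[[r]]))
    expect_identical(a$biases[[r]]@heights, b$biases[[r]]@heights)
  }
})

test_that("degenerate ladders reduce to plain metadynamics", {
  dw <- toyPotential("double-well-1d", a = 5)
  one <- runPTMetaD(dw, 300, metadParams(temperature = 300), nSteps = 2e4,
                    exchangeStride = 1000, seed = 7, friction = 50,
                    recordStride = 10)
  ref <- runMetadynamics(dw, metadParams(temperature = 300), nSteps = 2e4,
                         seed = 7, friction = 50, recordStride = 10)
  expect_identical(trajectoryData(one$trajectories[[1]]),
                   trajectoryData(ref$trajectory))
  # two replicas at (nearly) equal temperature without bias: all accepted
  run <- runPTMetaD(toyPotential("harmonic", k = 10), c(300, 300 + 1e-9),
                    metadParams(height = 1e-12), nSteps = 2e4,
                    exchangeStride = 1000, seed = 1, recordStride = 10)
  expect_equal(unname(run$ladder@accepts), unname(run$ladder@attempts))
  # stride/pace coupling is rejected, never silently resolved
  expect_error(runPTMetaD(dw, c(300, 400), metadParams(pace = 300),
                          nSteps = 1e4, exchangeStride = 1000, seed = 1),
               "multiple of the deposition pace")
})
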