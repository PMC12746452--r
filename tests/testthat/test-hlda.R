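mkStats <- function(mu, sigma, n = 100L) list(mu = mu, sigma = sigma, n = n)

test_that("class statistics use the unbiased covariance", {
  ser <- DescriptorSeries(rbind(rep(0, 6), c(2, rep(0, 5))),
                          label = c("A", "A"))
  st <- classStatistics(ser, "A")
  expect_equal(unname(st$mu), c(1, rep(0, 5)))
  expect_equal(st$sigma[1, 1], 2)          # (n-1) denominator
  same <- DescriptorSeries(rbind(rep(1, 6), rep(1, 6)), label = c("A", "A"))
  expect_equal(classStatistics(same, "A")$sigma, matrix(0, 6, 6),
               ignore_attr = TRUE)
  expect_error(classStatistics(ser, "B"), ">= 2 samples")
  # planted covariance recovered at n = 5000
  spec <- twoStateSpec(rep(0, 6), rep(1, 6), diag(6) * 2, diag(6),
                       nA = 5000, nB = 2, seed = 12)
  st2 <- classStatistics(sampleTwoStateDescriptors(spec), "A")
  expect_lt(norm(st2$sigma - diag(6) * 2, "F"), 0.1 * norm(diag(6) * 2, "F"))
})

test_that("between-class scatter is the rank-1 outer product", {
  a <- mkStats(c(1, rep(0, 5)), diag(6)); b <- mkStats(rep(0, 6), diag(6))
  Sb <- betweenScatter(a, b)
  expect_equal(Sb[1, 1], 1)
  expect_equal(sum(abs(Sb)) - Sb[1, 1], 0)
  expect_equal(betweenScatter(a, a), matrix(0, 6, 6))
  set.seed(3)
  mu1 <- rnorm(6); mu2 <- rnorm(6)
  S <- betweenScatter(mkStats(mu1, diag(6)), mkStats(mu2, diag(6)))
  expect_equal(sum(diag(S)), sum((mu1 - mu2)^2))
  expect_error(betweenScatter(mkStats(rnorm(4), diag(4)), a), "dimension")
})

test_that("harmonic within-class scatter matches matrix arithmetic", {
  I6 <- diag(6)
  a <- mkStats(rep(0, 6), I6); b <- mkStats(rep(1, 6), I6)
  expect_equal(harmonicWithinScatter(a, b, ridge = 0), I6 / 2)
  a2 <- mkStats(c(0, 0), diag(c(1, 3))); b2 <- mkStats(c(1, 1), diag(c(3, 1)))
  expect_equal(harmonicWithinScatter(a2, b2, ridge = 0), diag(c(3 / 4, 3 / 4)))
  set.seed(4)
  S <- randomSPD(6)
  expect_equal(harmonicWithinScatter(mkStats(rep(0, 6), S),
                                     mkStats(rep(0, 6), S), ridge = 0), S / 2,
               tolerance = 1e-10)
  zero <- mkStats(rep(0, 2), matrix(0, 2, 2))
  expect_error(harmonicWithinScatter(zero, zero, ridge = 0), "ridge")
})

test_that("the discriminant direction solves the generalized eigenproblem", {
  a <- mkStats(c(1, rep(0, 5)), diag(6)); b <- mkStats(rep(0, 6), diag(6))
  m <- hldaDirection(a, b, ridge = 0)
  expect_equal(abs(m@weights), c(1, rep(0, 5)), tolerance = 1e-10)
  expect_equal(m@eigenvalues[1], 2, tolerance = 1e-10)
  expect_lt(abs(sqrt(sum(m@weights^2)) - 1), 1e-10)
  # sign convention: the largest-magnitude weight is negative
  expect_lt(m@weights[which.max(abs(m@weights))], 0)
  # anisotropic closed form: direction proportional to (1/s1^2, 1/s2^2)
  a2 <- mkStats(c(0, 0), diag(c(4, 1))); b2 <- mkStats(c(-1, -1), diag(c(4, 1)))
  m2 <- hldaDirection(a2, b2, ridge = 0)
  ref <- c(1 / 4, 1) / sqrt(sum(c(1 / 4, 1)^2))
  expect_equal(abs(m2@weights), ref, tolerance = 1e-10)
  # degenerate case: equal means
  dg <- hldaDirection(a, a, ridge = 0)
  expect_true(dg@degenerate)
  expect_equal(dg@eigenvalues[1], 0)
})

test_that("eigen-solver agrees with the closed form on random instances", {
  set.seed(21)
  for (k in 1:50) {
    SA <- randomSPD(6); SB <- randomSPD(6)
    muA <- rnorm(6); muB <- rnorm(6)
    m <- hldaDirection(mkStats(muA, SA), mkStats(muB, SB), ridge = 0)
    Sw <- solve(solve(SA) + solve(SB))
    wRef <- solve(Sw, muA - muB)
    wRef <- wRef / sqrt(sum(wRef^2))
    expect_gte(abs(sum(m@weights * wRef)), 0.9999)
    lamRef <- as.numeric(t(muA - muB) %*% solve(Sw, muA - muB))
    expect_lt(abs(m@eigenvalues[1] - lamRef) / lamRef, 1e-8)
    # rank-1 spectrum
    expect_lt(max(abs(m@eigenvalues[-1])), 1e-8 * m@eigenvalues[1])
    # scaling both covariances leaves the direction unchanged
    m2 <- hldaDirection(mkStats(muA, 3 * SA), mkStats(muB, 3 * SB), ridge = 0)
    expect_gte(abs(sum(m@weights * m2@weights)), 1 - 1e-10)
    expect_equal(m2@eigenvalues[1], m@eigenvalues[1] / 3, tolerance = 1e-8)
  }
})

test_that("well-separated planted classes project far apart", {
  spec <- twoStateSpec(c(25, 14, 18, 0.5, 0.5, 0.5),
                       c(2, 1, 1.5, 0.1, 0.2, 0.3),
                       diag(6) * 0.4, diag(6) * 0.6,
                       nA = 4000, nB = 4000, seed = 2)
  ser <- sampleTwoStateDescriptors(spec)
  m <- hldaFit(ser, labels = c("A", "B"))
  s <- projectCV(m, ser)
  sA <- s[frameLabels(ser) == "A"]; sB <- s[frameLabels(ser) == "B"]
  pooled <- sqrt((var(sA) + var(sB)) / 2)
  expect_gte(abs(mean(sA) - mean(sB)), 5 * pooled)
  expect_gte(abs(sum(m@weights * plantedDirection(spec))), 0.99)
})

test_that("projection is the plain linear functional of the descriptors", {
  e1 <- rep(0, 6); e1[1] <- -1   # sign convention: largest weight negative
  m <- new("HLDAModel", weights = e1, eigenvalues = c(1, rep(0, 5)),
           eigenvectors = diag(6), separation = 1,
           descriptorNames = paste0("d", 1:6), degenerate = FALSE)
  expect_equal(projectCV(m, matrix(c(3, 0, 0, 0, 0, 0), 1)), -3)
  expect_equal(projectCV(m, matrix(0, 4, 6)), rep(0, 4))
  # the published weight vector applied to the all-ones descriptor
  w <- c(-0.026, -0.406, -0.540, -0.735, -0.021, -0.043)
  mw <- new("HLDAModel", weights = w, eigenvalues = c(1, rep(0, 5)),
            eigenvectors = diag(6), separation = 1,
            descriptorNames = paste0("d", 1:6), degenerate = FALSE)
  expect_equal(projectCV(mw, matrix(1, 1, 6)), sum(w))
  expect_equal(sum(w), -1.771)
  # refuses silently reordered descriptors
  x <- matrix(1, 1, 6)
  colnames(x) <- paste0("d", c(2, 1, 3:6))
  expect_error(projectCV(mw, x), "reordering")
})

test_that("CV definitions round-trip through the text format", {
  spec <- twoStateSpec(rep(0, 6), rep(1, 6), diag(6), diag(6),
                       nA = 500, nB = 500, seed = 6)
  m <- hldaFit(sampleTwoStateDescriptors(spec), labels = c("A", "B"))
  txt <- exportCVDefinition(m)
  expect_length(grep("^d[1-6] ", txt), 6L)
  back <- parseCVDefinition(txt)
  x <- matrix(rnorm(60), 10, 6)
  expect_identical(projectCV(back, x), projectCV(m, x))
  dg <- hldaDirection(mkStats(rep(0, 6), diag(6)),
                      mkStats(rep(0, 6), diag(6)))
  expect_error(exportCVDefinition(dg), "degenerate")
})
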