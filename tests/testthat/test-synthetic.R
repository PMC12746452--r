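test_that("ideal helix builder reproduces canonical alpha geometry", {
  h <- idealHelix30()
  expect_equal(nResidues(h), 30L)
  ca <- frameCoords(h)[atomTable(h)$name == "CA", ]
  bond <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(bond - 0.38) / 0.38 < 0.02))
  # axial displacement over 18 residues at the default 0.15 nm rise
  expect_equal(ca[19, 3] - ca[1, 3], 18 * 0.15, tolerance = 1e-10)
  # dihedrals are uniform along the chain and within 2 degrees of the
  # canonical alpha values the template construction itself uses
  d <- backboneDihedrals(h)
  phis <- d$phi[!is.na(d$phi)]; psis <- d$psi[!is.na(d$psi)]
  expect_lt(diff(range(phis)), 1e-6)
  expect_lt(diff(range(psis)), 1e-6)
  expect_lt(abs(phis[1] - (-64.714)), 2)
  expect_lt(abs(psis[1] - (-41.931)), 2)
  expect_error(buildIdealHelix(5L), "6")
})

test_that("melting rebuilds the C-terminal fraction at extended dihedrals", {
  h <- idealHelix30()
  expect_identical(meltHelix(h, 0), h)
  half <- meltHelix(h, 0.5)
  # residues 1-15 untouched (ceiling rule melts 16-30)
  keep <- atomTable(h)$resid <= 15
  expect_equal(frameCoords(half)[keep, ], frameCoords(h)[keep, ])
  dme <- backboneDihedrals(half)
  expect_equal(dme$phi[17:29], rep(-135, 13), tolerance = 1e-8)
  expect_equal(dme$psi[16:29], rep(135, 14), tolerance = 1e-8)
  # connectivity preserved across the junction
  ca <- frameCoords(half)[atomTable(half)$name == "CA", ]
  bond <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(bond > 0.25 & bond < 0.55))
  # full melt: alpha content per segment collapses
  ext <- extendedChain30()
  expect_lt(alphaRmsd(ext, c(1, 30)) / 25, 0.05)
})

test_that("two-state sampler hits the planted moments", {
  spec <- twoStateSpec(rep(0, 6), c(0, 0, 0, 1, 0, 0), diag(6), diag(6),
                       nA = 5000, nB = 5000, seed = 1)
  ser <- sampleTwoStateDescriptors(spec)
  a <- descriptorValues(ser)[frameLabels(ser) == "A", ]
  b <- descriptorValues(ser)[frameLabels(ser) == "B", ]
  expect_true(all(abs(colMeans(b) - colMeans(a) - c(0, 0, 0, 1, 0, 0)) < 0.05))
  # covariance converges in Frobenius norm as n grows
  frob <- function(n) {
    s <- sampleTwoStateDescriptors(twoStateSpec(rep(0, 6), rep(1, 6),
                                                diag(6), diag(6),
                                                nA = n, nB = 2, seed = 3))
    x <- descriptorValues(s)[frameLabels(s) == "A", ]
    norm(cov(x) - diag(6), "F")
  }
  expect_lt(frob(5000), frob(500))
  # minimum class size
  tiny <- sampleTwoStateDescriptors(twoStateSpec(rep(0, 6), rep(1, 6),
                                                 diag(6), diag(6),
                                                 nA = 2, nB = 2, seed = 1))
  expect_identical(sum(frameLabels(tiny) == "A"), 2L)
  # non-SPD covariance is rejected by name
  bad <- diag(6); bad[1, 1] <- -1
  expect_error(twoStateSpec(rep(0, 6), rep(1, 6), bad, diag(6)), "sigmaA")
  # reproducibility
  expect_identical(descriptorValues(sampleTwoStateDescriptors(spec)),
                   descriptorValues(sampleTwoStateDescriptors(spec)))
})

test_that("toy potential gradients match finite differences", {
  set.seed(11)
  pots <- list(toyPotential("harmonic", k = 7, x0 = 0.3),
               toyPotential("double-well-1d", a = 6, b = -1.5),
               toyPotential("double-funnel-2d"))
  for (pot in pots) {
    for (rep in 1:10) {
      x <- runif(pot@dim, -1.5, 1.5)
      g <- potentialGradient(pot, x)
      h <- 1e-6
      gnum <- vapply(seq_len(pot@dim), function(d) {
        dx <- rep(0, pot@dim); dx[d] <- h
        (potentialEnergy(pot, if (pot@dim == 1) x + dx else rbind(x + dx)) -
         potentialEnergy(pot, if (pot@dim == 1) x - dx else rbind(x - dx))) / (2 * h)
      }, numeric(1))
      expect_equal(g, gnum, tolerance = 1e-5)
    }
  }
})

test_that("overdamped Langevin sampler obeys equipartition and its contracts", {
  pot <- toyPotential("harmonic", k = 10)
  tr <- langevinSample(pot, temperature = 300, nSteps = 5e5, seed = 2,
                       recordStride = 10)
  expect_lt(abs(var(cvValues(tr)) / (kBT(300) / 10) - 1), 0.05)
  # zero temperature: deterministic descent to the nearest minimum (x = +L)
  dw <- toyPotential("double-well-1d", a = 5)
  t0 <- langevinSample(dw, temperature = 0, nSteps = 5000, seed = 1,
                       x0 = 0.05, friction = 50)
  expect_equal(tail(cvValues(t0), 1), 0.15, tolerance = 1e-3)
  # bit-identical under the same seed
  a <- langevinSample(pot, nSteps = 1000, seed = 9)
  b <- langevinSample(pot, nSteps = 1000, seed = 9)
  expect_identical(trajectoryData(a), trajectoryData(b))
  # divergence raises an actionable error
  expect_error(langevinSample(toyPotential("harmonic", k = -2000),
                              nSteps = 10000, seed = 1, x0 = 0.5),
               "smaller dt")
})

test_that("Langevin double-well populations match the Boltzmann ratio", {
  dw <- makeDoubleWell(deltaF_kT = 1.5, barrier = 4, temperature = 300)
  tr <- langevinSample(dw$potential, temperature = 300, nSteps = 2e6,
                       seed = 4, friction = 50, recordStride = 10)
  x <- cvValues(tr)
  pRight <- mean(x > 0)
  ratio <- pRight / (1 - pRight)
  est <- log(ratio)             # = +deltaF in kT if right well deeper
  n_eff <- 2e5 / 50             # conservative decorrelation allowance
  se <- sqrt(1 / (pRight * (1 - pRight) * n_eff))
  expect_lt(abs(est - dw$deltaF_kT), 3 * se + 0.1)
})

test_that("planted FES grids are recovered exactly by exhaustive search", {
  edges <- list(seq(-2, 2, length.out = 41), seq(-2, 2, length.out = 41))
  pf <- plantFES(list(list(pos = c(-1, 0), depth = 0),
                      list(pos = c(1, 0.5), depth = 1)),
                 saddles = 6, edges = edges)
  fes <- pf$fes
  b <- findMinima(fes)
  expect_identical(nrow(b), 2L)
  p <- minimumEnergyPath(fes, b, 1, 2)
  expect_equal(p$pathMax, 6)
  expect_error(plantFES(list(list(pos = c(0, 0), depth = 0)), numeric(0),
                        edges), "2 minima")
  expect_error(plantFES(list(list(pos = c(0, 0), depth = 0),
                             list(pos = c(0.05, 0), depth = 0)),
                        saddles = 6, edges = edges), "unresolvable")
  # flat grid: single plateau representative
  flat <- matrixFES(matrix(0, 6, 6))
  expect_identical(nrow(findMinima(flat)), 1L)
})
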