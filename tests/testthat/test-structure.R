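test_that("dihedral-window secondary structure separates helix from coil", {
  h <- idealHelix30()
  ss <- assignSecondaryStructure(h)
  expect_true(all(ss[2:29] == "H"))        # interior residues helical
  expect_true(all(ss[c(1, 30)] == "C"))    # termini lack a dihedral
  ext <- extendedChain30()
  expect_true(all(assignSecondaryStructure(ext) == "C"))
  # a 3-residue helical stretch flanked by coil fails the run-length rule
  mixed <- meltHelix(h, 27 / 30)           # only residues 1-3 keep alpha
  expect_true(all(assignSecondaryStructure(mixed) == "C"))
  # SS populations sum to one per frame
  pops <- ssPopulations(foldedBundle())
  expect_equal(pops$perFrame$helixFraction + pops$perFrame$coilFraction, 1)
})

test_that("per-helix helicity reproduces the sequential-melting signature", {
  b <- foldedBundle()
  hel <- helixDefinitions()
  expect_equal(unname(helicityPerHelix(b, hel, reference = b)), rep(1, 3))
  fullMelt <- meltHelix(b, 1)
  expect_equal(unname(helicityPerHelix(fullMelt, hel, reference = b)),
               rep(0, 3))
  # helix III melted, I and II intact: (1, 1, 0)
  m3 <- meltHelix(b, 27 / 76)
  hts <- helicityPerHelix(m3, hel, reference = b)
  expect_gt(hts["I"], 0.95)
  expect_gt(hts["II"], 0.95)
  expect_lt(hts["III"], 0.05)
  # a reference with no helical residues is rejected
  expect_error(helicityPerHelix(b, hel, reference = fullMelt), "zero helical")
})

test_that("Shrake-Rupley quadrature matches analytic sphere areas", {
  a1 <- sasaAtomAreas(matrix(0, 1, 3), "X", probe = 0.14, nPoints = 960,
                      radii = c(X = 0.16))
  expect_lt(abs(a1 - 4 * pi * 0.30^2) / (4 * pi * 0.30^2), 0.01)
  # two atoms far apart: no occlusion
  a2 <- sasaAtomAreas(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "C"))
  expect_lt(abs(sum(a2) - 2 * 4 * pi * 0.31^2) / (2 * 4 * pi * 0.31^2), 0.01)
  # an atom caged by neighbours loses almost all area
  cage <- as.matrix(expand.grid(c(-0.25, 0, 0.25), c(-0.25, 0, 0.25),
                                c(-0.25, 0, 0.25)))
  xyz <- rbind(c(0, 0, 0), cage[rowSums(abs(cage)) > 0, ])
  a3 <- sasaAtomAreas(xyz, rep("C", nrow(xyz)))
  expect_lt(a3[1] / (4 * pi * 0.31^2), 0.005)
  # quadrature convergence on the helix fixture
  h <- idealHelix30()
  sA <- shrakeRupleySasa(h, nPoints = 480)
  sB <- shrakeRupleySasa(h, nPoints = 960)
  expect_lt(abs(sB$total - sA$total) / sB$total, 0.005)
  expect_error(sasaAtomAreas(matrix(0, 1, 3), "Zz"), "Zz")
  expect_error(shrakeRupleySasa(h, nPoints = 50), ">= 92")
})

test_that("SASA subtotals are exact sums of their members", {
  b <- foldedBundle()
  s <- shrakeRupleySasa(b, nPoints = 240)
  expect_equal(s$total, sum(s$perResidue$area))
  expect_equal(s$hydrophobic,
               sum(s$perResidue$area[s$perResidue$resname %in%
                                     hydrophobicResidues()]))
  expect_equal(s$apr, sum(s$perResidue$area[s$perResidue$resid %in% 42:48]))
  expect_lte(s$hydrophobic, s$total)
  expect_lte(s$apr, s$total)
  expect_true(all(s$perResidue$area >= 0))
})

test_that("helix distance matrices respond only to the moved helix", {
  b <- foldedBundle()
  hel <- helixDefinitions()
  M <- helixDistanceMatrix(b, hel)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(0, 3))
  # rigid-body move of the whole frame: identical matrix
  bR <- transformStructure(b, rotation = randomRotation(),
                           translation = c(1, 2, 3))
  expect_equal(helixDistanceMatrix(bR, hel), M, tolerance = 1e-9)
  # displacing helix III changes only the (1,3) and (2,3) entries
  b3 <- displaceSegment(b, c(50L, 76L), c(0, 0, 1),
                        rebridge = list(c(48L, 49L)))
  M3 <- helixDistanceMatrix(b3, hel)
  expect_equal(M3["I", "II"], M["I", "II"], tolerance = 1e-9)
  expect_gt(abs(M3["I", "III"] - M["I", "III"]), 0.1)
  expect_gt(abs(M3["II", "III"] - M["II", "III"]), 0.1)
})

test_that("the core-exposure fixture shows localized APR unmasking", {
  fx <- aprExposureFixture()
  s0 <- shrakeRupleySasa(fx$folded, nPoints = 240)
  s1 <- shrakeRupleySasa(fx$exposed, nPoints = 240)
  expect_gt(s1$apr, s0$apr)                          # APR strictly exposed
  expect_lt(abs(s1$total - s0$total) / s0$total, 0.10)  # fold intact
})

test_that("basin reports aggregate the ensemble observables", {
  b <- foldedBundle()
  hel <- helixDefinitions()
  rep1 <- basinReport(b, 1L, hel, reference = b, sasaPoints = 240)
  expect_equal(unname(rep1$helicity), rep(1, 3))
  expect_equal(rep1$sasaTotal, shrakeRupleySasa(b, nPoints = 240)$total)
  melted <- meltHelix(b, 1)
  rep2 <- basinReport(melted, 2L, hel, reference = b, sasaPoints = 240)
  expect_lt(rep2$ssPopulation["helix"], 0.02)
  expect_gt(rep2$ssPopulation["coil"], 0.98)
  expect_gt(rep2$rg, rep1$rg)    # extended chain is less compact
})

test_that("helix content decreases monotonically across the melting ladder", {
  b <- foldedBundle()
  temps <- c(300, 340, 380, 420, 450)
  sets <- lapply(seq_along(temps), function(k) {
    jitterEnsemble(meltHelix(b, (k - 1) / 4), 4L, 0.01, seed = k)
  })
  prof <- temperatureSSProfile(sets, temps)
  expect_identical(prof$temperature, temps)
  expect_true(all(diff(prof$helixFraction) <= 1e-9))
  expect_true(all(prof$helixFraction + prof$coilFraction == 1))
  # identical frames at all temperatures: constant profile
  flatProf <- temperatureSSProfile(list(b, b, b), c(300, 350, 400))
  expect_lt(diff(range(flatProf$helixFraction)), 1e-12)
  # single frame per temperature: SE is the undefined sentinel
  expect_true(all(is.na(temperatureSSProfile(list(b, b), c(300, 400))$se)))
  expect_error(temperatureSSProfile(list(b), 300), "2 temperatures")
})
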