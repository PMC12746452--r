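test_that("basin finding handles wells, plateaus and planted fixtures", {
  # single quadratic well: one basin at the bottom bin
  x <- seq(-1, 1, length.out = 21)
  E <- outer(x^2, x^2, `+`)
  f <- matrixFES(E * 5)
  b <- findMinima(f)
  expect_identical(nrow(b), 1L)
  expect_identical(c(b$i1, b$i2), c(11L, 11L))
  # planted two-minimum fixture: basins at the planted nodes
  edges <- list(seq(-2, 2, length.out = 41), seq(-2, 2, length.out = 41))
  pf <- plantFES(list(list(pos = c(-1, -0.5), depth = 0),
                      list(pos = c(0.8, 0.9), depth = 1.5)),
                 saddles = 5, edges = edges)
  b2 <- findMinima(pf$fes)
  expect_identical(nrow(b2), 2L)
  expect_identical(unname(c(b2$i1[1], b2$i2[1])), pf$nodes[[1]])
  expect_identical(unname(c(b2$i1[2], b2$i2[2])), pf$nodes[[2]])
  expect_equal(b2$energy, c(0, 1.5))
  # label stability: re-running is bit-identical
  expect_identical(findMinima(pf$fes), findMinima(pf$fes))
  # flat grid: a single plateau representative at the lexicographic head
  flat <- matrixFES(matrix(1, 5, 7))
  bf <- findMinima(flat)
  expect_identical(nrow(bf), 1L)
  expect_identical(c(bf$i1, bf$i2), c(1L, 1L))
  # all-masked grid errors
  allm <- foldscape:::makeFESGrid(
    axes = list(list(name = "s", edges = 0:3)),
    values = rep(NA_real_, 3), mask = rep(TRUE, 3), unit = "RT",
    temperature = 300)
  expect_error(findMinima(allm), "masked")
})

test_that("shallow basins are pruned by persistence", {
  # a 1D profile with a deep well, a shallow dimple, and a deep second well
  v <- c(5, 0, 3.4, 3, 3.5, 5, 1, 6) # dimple at 3 has persistence 0.4
  f1 <- foldscape:::makeFESGrid(
    axes = list(list(name = "s", edges = seq(0, 8))),
    values = v, mask = rep(FALSE, 8), unit = "RT", temperature = 300)
  expect_identical(nrow(findMinima(f1, minDepth = 0.5)), 2L)
  expect_identical(nrow(findMinima(f1, minDepth = 0.3)), 3L)
})

test_that("minimax paths equal exhaustive enumeration on random grids", {
  set.seed(101)
  for (k in 1:40) {
    E <- matrix(runif(12, 0, 10), 3, 4)
    E[1, 1] <- 0; E[3, 4] <- 0.01
    f <- matrixFES(E)
    b <- findMinima(f, minDepth = 0)
    if (nrow(b) < 2) next
    src <- c(b$i1[1], b$i2[1]); dst <- c(b$i1[2], b$i2[2])
    p <- minimumEnergyPath(f, b, b$label[1], b$label[2])
    ref <- bruteForceMinimax(fesValues(f), src, dst)
    expect_equal(p$pathMax, ref, tolerance = 1e-12)
    # minimax symmetry
    pBack <- minimumEnergyPath(f, b, b$label[2], b$label[1])
    expect_equal(pBack$pathMax, p$pathMax, tolerance = 1e-12)
    # endpoints never exceed the path maximum
    expect_lte(max(p$energies[1], p$energies[length(p$energies)]), p$pathMax)
  }
})

test_that("paths route through the low saddle, not the high ridge", {
  edges <- list(seq(-2, 2, length.out = 33), seq(-2, 2, length.out = 33))
  pf <- plantFES(list(list(pos = c(-1, 0), depth = 0),
                      list(pos = c(1, 0), depth = 0.5)),
                 saddles = 2.5, edges = edges)
  b <- findMinima(pf$fes)
  p <- minimumEnergyPath(pf$fes, b, 1, 2)
  expect_equal(p$pathMax, 2.5)
  # basins separated by a single saddle node: three-node path contract
  f2 <- foldscape:::makeFESGrid(
    axes = list(list(name = "s", edges = 0:3)),
    values = c(0, 5, 1), mask = rep(FALSE, 3), unit = "RT",
    temperature = 300)
  b2 <- findMinima(f2, minDepth = 0)
  p2 <- minimumEnergyPath(f2, b2, 1, 2)
  expect_identical(nrow(p2$nodes), 3L)
  expect_equal(p2$pathMax, 5)
  # raising an off-path node's energy never changes the path maximum
  vRaised <- fesValues(pf$fes)
  offPath <- which(vRaised > 4 & !is.na(vRaised))[1]
  vRaised[offPath] <- vRaised[offPath] + 50
  fRaised <- foldscape:::makeFESGrid(pf$fes@axes, vRaised,
                                     matrix(FALSE, nrow(vRaised), ncol(vRaised)),
                                     "RT", 300)
  bR <- findMinima(fRaised)
  pR <- minimumEnergyPath(fRaised, bR, 1, 2)
  expect_equal(pR$pathMax, p$pathMax)
  # masked separation is reported
  v <- c(0, NA, 1)
  fm <- foldscape:::makeFESGrid(
    axes = list(list(name = "s", edges = 0:3)),
    values = c(0, NA, 1), mask = c(FALSE, TRUE, FALSE), unit = "RT",
    temperature = 300)
  bm <- findMinima(fm, minDepth = 0)
  expect_error(minimumEnergyPath(fm, bm, 1, 2), "masked")
})

test_that("barrier tables report forward and reverse legs in RT", {
  edges <- list(seq(-2, 2, length.out = 41), seq(-2, 2, length.out = 41))
  pf <- plantFES(list(list(pos = c(-1, 0), depth = 0),
                      list(pos = c(1, 0.4), depth = 1)),
                 saddles = 6, edges = edges)
  b <- findMinima(pf$fes)
  pFwd <- minimumEnergyPath(pf$fes, b, 1, 2)
  barFwd <- barriersAlongPath(pFwd, b)
  expect_equal(barFwd$legs$barrier, 6)
  pRev <- minimumEnergyPath(pf$fes, b, 2, 1)
  barRev <- barriersAlongPath(pRev, b)
  expect_equal(barRev$legs$barrier, 5)
  expect_true(all(barFwd$legs$barrier >= 0))
  # a path visiting fewer than 2 basins errors
  short <- pFwd; short$nodes <- pFwd$nodes[2:3, , drop = FALSE]
  short$energies <- pFwd$energies[2:3]
  expect_error(barriersAlongPath(short, b), "fewer than 2")
})

test_that("frames map to the basins that generated them", {
  edges <- list(seq(-2, 2, length.out = 41), seq(-2, 2, length.out = 41))
  pf <- plantFES(list(list(pos = c(-1, 0), depth = 0),
                      list(pos = c(1, 0.5), depth = 1)),
                 saddles = 6, edges = edges)
  b <- findMinima(pf$fes)
  # frame exactly at a basin node
  at1 <- assignFramesToBasins(matrix(c(b$c1[1], b$c2[1]), 1), b, pf$fes)
  expect_identical(at1[["1"]], 1L)
  # planted two-well samples: assignment matches the generating well
  set.seed(6)
  n <- 200
  wellId <- rep(1:2, each = n)
  pts <- rbind(cbind(rnorm(n, -1, 0.12), rnorm(n, 0, 0.12)),
               cbind(rnorm(n, 1, 0.12), rnorm(n, 0.5, 0.12)))
  asg <- assignFramesToBasins(pts, b, pf$fes, radius = 4L)
  got <- rep(NA_integer_, 2 * n)
  got[asg[["1"]]] <- 1L; got[asg[["2"]]] <- 2L
  ok <- !is.na(got)
  expect_gte(mean(got[ok] == wellId[ok]), 0.95)
  # frames on masked bins stay unassigned
  vm <- foldscape:::makeFESGrid(
    axes = list(list(name = "s", edges = 0:3)),
    values = c(0, 2, NA), mask = c(FALSE, FALSE, TRUE), unit = "RT",
    temperature = 300)
  bm <- findMinima(vm, minDepth = 0)
  am <- assignFramesToBasins(2.5, bm, vm)
  expect_identical(am$unassigned, 1L)
})
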