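#' Dihedral-window secondary-structure assignment
#'
#' Residue i is helical (H) when its backbone dihedrals fall in the alpha
#' window \code{phi in [-100, -30]} and \code{psi in [-80, -5]} degrees and
#' it belongs to a run of at least \code{minRun} consecutive such residues;
#' otherwise coil (C). Chain-terminal residues lacking a dihedral are coil.
#'
#' @param structure \code{BackboneStructure}.
#' @param frame frame index.
#' @param phiWindow,psiWindow degrees.
#' @param minRun minimum helical run length.
#' @return character vector over residues, values \code{"H"}/\code{"C"}.
#' @export
assignSecondaryStructure <- function(structure, frame = 1L,
                                     phiWindow = c(-100, -30),
                                     psiWindow = c(-80, -5), minRun = 4L) {
  if (nResidues(structure) < 3L) stop("need at least 3 residues")
  dih <- backboneDihedrals(structure, frame)
  inWin <- !is.na(dih$phi) & !is.na(dih$psi) &
    dih$phi >= phiWindow[1] & dih$phi <= phiWindow[2] &
    dih$psi >= psiWindow[1] & dih$psi <= psiWindow[2]
  ss <- rep("C", nrow(dih))
  r <- rle(inWin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= minRun) ss[starts[k]:ends[k]] <- "H"
  }
  names(ss) <- dih$resid
  ss
}

#' Per-frame and ensemble secondary-structure populations
#'
#' @param structure multi-frame \code{BackboneStructure}.
#' @param ... passed to \code{\link{assignSecondaryStructure}}.
#' @return list with \code{perFrame} (data.frame: frame, helixFraction,
#'   coilFraction) and \code{mean} fractions.
#' @export
ssPopulations <- function(structure, ...) {
  nf <- nFrames(structure)
  fr <- vapply(seq_len(nf), function(f) {
    ss <- assignSecondaryStructure(structure, frame = f, ...)
    mean(ss == "H")
  }, numeric(1))
  perFrame <- data.frame(frame = seq_len(nf), helixFraction = fr,
                         coilFraction = 1 - fr)
  list(perFrame = perFrame,
       mean = c(helix = mean(fr), coil = 1 - mean(fr)))
}

#' Helicity per helix relative to a folded reference
#'
#' For each helix range: the mean over frames of the number of H-assigned
#' residues in the range divided by the count in the folded reference.
#' Values above 1 (more helical than the reference) are reported as is.
#'
#' @param structure multi-frame \code{BackboneStructure}.
#' @param helices \code{\link{helixDefinitions}}.
#' @param reference folded single-frame \code{BackboneStructure} sharing the
#'   residue indexing.
#' @return named numeric vector of per-helix helicity fractions.
#' @export
helicityPerHelix <- function(structure, helices = helixDefinitions(),
                             reference) {
  ssRef <- assignSecondaryStructure(reference)
  refCount <- vapply(helices, function(rng) {
    ids <- as.integer(names(ssRef))
    n <- sum(ssRef[ids >= rng[1] & ids <= rng[2]] == "H")
    if (n == 0L) stop("reference helix has zero helical residues")
    n
  }, numeric(1))
  nf <- nFrames(structure)
  counts <- vapply(seq_len(nf), function(f) {
    ss <- assignSecondaryStructure(structure, frame = f)
    ids <- as.integer(names(ss))
    vapply(helices, function(rng)
      sum(ss[ids >= rng[1] & ids <= rng[2]] == "H"), numeric(1))
  }, numeric(length(helices)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(helices))
  out <- rowMeans(counts) / refCount
  names(out) <- names(helices)
  out
}

## van der Waals radii by element, nm (standard published values)
.vdwRadii <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120)

## deterministic golden-spiral quadrature points on the unit sphere
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Hydrophobic residue set used for SASA subtotals
#' @return character vector of 3-letter codes.
#' @export
hydrophobicResidues <- function() {
  c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "CYS")
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Spherical quadrature with probe-inflated van der Waals spheres: for each
#' atom, test points on its inflated sphere are accessible when outside
#' every neighbouring inflated sphere; the per-atom area is the accessible
#' fraction of \eqn{4\pi(r + r_{probe})^2}. Per-residue sums and declared
#' subset subtotals (all, hydrophobic, aggregation-prone region) are
#' reported.
#'
#' @param structure \code{BackboneStructure}.
#' @param frame frame index.
#' @param probe probe radius, nm (water: 0.14).
#' @param nPoints quadrature points per atom (>= 92).
#' @param aprRange aggregation-prone residue range (1-based inclusive).
#' @param hydrophobic 3-letter codes counted as hydrophobic.
#' @param radii named vdW radius table by element, nm.
#' Per-atom Shrake-Rupley accessible areas
#'
#' The quadrature core: test points on each probe-inflated sphere are
#' accessible when outside every neighbouring inflated sphere.
#'
#' @param xyz n x 3 coordinate matrix, nm.
#' @param elements element symbols, length n.
#' @param probe probe radius, nm.
#' @param nPoints quadrature points per atom.
#' @param radii named vdW radius table by element, nm.
#' @return numeric vector of per-atom areas, nm^2.
#' @export
sasaAtomAreas <- function(xyz, elements, probe = 0.14, nPoints = 960L,
                          radii = .vdwRadii) {
  if (nPoints < 92L) stop("nPoints must be >= 92")
  unknown <- setdiff(unique(elements), names(radii))
  if (length(unknown))
    stop(sprintf("no van der Waals radius for element '%s'", unknown[1]))
  xyz <- as.matrix(xyz)
  R <- radii[elements] + probe
  nat <- nrow(xyz)
  sphere <- .spherePoints(nPoints)
  area <- numeric(nat)
  d2 <- as.matrix(dist(xyz))^2
  for (i in seq_len(nat)) {
    nbr <- which(d2[i, ] < (R[i] + R)^2 & seq_len(nat) != i)
    pts <- sweep(sphere * R[i], 2, xyz[i, ], "+")
    if (length(nbr)) {
      acc <- rep(TRUE, nPoints)
      for (j in nbr) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
               (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > R[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    area[i] <- frac * 4 * pi * R[i]^2
  }
  area
}

#' Shrake-Rupley solvent-accessible surface area of a structure
#'
#' Per-residue sums of \code{\link{sasaAtomAreas}} plus declared subset
#' subtotals: all residues, a hydrophobic set, and the aggregation-prone
#' region (APR).
#'
#' @param structure \code{BackboneStructure}.
#' @param frame frame index.
#' @param probe probe radius, nm (water: 0.14).
#' @param nPoints quadrature points per atom (>= 92).
#' @param aprRange aggregation-prone residue range (1-based inclusive).
#' @param hydrophobic 3-letter codes counted as hydrophobic.
#' @param radii named vdW radius table by element, nm.
#' @return list of class \code{sasaResult}: \code{perResidue} (data.frame),
#'   \code{total}, \code{hydrophobic}, \code{apr} (nm^2), \code{probe}.
#' @export
shrakeRupleySasa <- function(structure, frame = 1L, probe = 0.14,
                             nPoints = 960L, aprRange = c(42L, 48L),
                             hydrophobic = hydrophobicResidues(),
                             radii = .vdwRadii) {
  at <- structure@atoms
  xyz <- frameCoords(structure, frame)
  area <- sasaAtomAreas(xyz, at$element, probe, nPoints, radii)
  perRes <- tapply(area, at$resid, sum)
  resid <- as.integer(names(perRes))
  resname <- at$resname[match(resid, at$resid)]
  perResidue <- data.frame(resid = resid, resname = resname,
                           area = as.numeric(perRes))
  out <- list(
    perResidue = perResidue,
    total = sum(perResidue$area),
    hydrophobic = sum(perResidue$area[perResidue$resname %in% hydrophobic]),
    apr = sum(perResidue$area[perResidue$resid >= aprRange[1] &
                              perResidue$resid <= aprRange[2]]),
    probe = probe, nPoints = nPoints)
  class(out) <- "sasaResult"
  out
}

#' Write per-residue SASA as a BED-like interval table
#'
#' Tab-separated columns \code{chain}, \code{start}, \code{end} (1-based
#' inclusive residue intervals), \code{resname}, \code{area_nm2}.
#'
#' @param sasa a \code{sasaResult} from \code{\link{shrakeRupleySasa}}.
#' @param file output path.
#' @param chain chain label.
#' @return \code{file}, invisibly.
#' @export
writeSasaIntervals <- function(sasa, file, chain = "A") {
  pr <- sasa$perResidue
  df <- data.frame(chain = chain, start = pr$resid, end = pr$resid,
                   resname = pr$resname, area_nm2 = pr$area)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Mean helix centre-of-mass distance matrix
#'
#' Symmetric 3x3 matrix of mean pairwise helix CA-centroid distances over
#' frames; zero diagonal.
#'
#' @param structure multi-frame \code{BackboneStructure}.
#' @param helices \code{\link{helixDefinitions}}.
#' @return 3x3 matrix, nm.
#' @export
helixDistanceMatrix <- function(structure, helices = helixDefinitions()) {
  nf <- nFrames(structure)
  nms <- names(helices)
  acc <- matrix(0, length(helices), length(helices),
                dimnames = list(nms, nms))
  for (f in seq_len(nf)) {
    for (a in seq_along(helices)) for (b in seq_along(helices)) {
      if (a < b) {
        d <- helixComDistance(structure, helices[[a]], helices[[b]], frame = f)
        acc[a, b] <- acc[a, b] + d
        acc[b, a] <- acc[b, a] + d
      }
    }
  }
  acc / nf
}

#' Per-basin structural ensemble report
#'
#' Aggregates, for one basin's frame ensemble: per-helix helicity relative
#' to the folded reference, secondary-structure populations, mean radius of
#' gyration, the 3x3 helix distance matrix, and SASA subtotals (total,
#' hydrophobic, aggregation-prone region).
#'
#' @param structure the basin's frames (\code{BackboneStructure}).
#' @param label basin label.
#' @param helices \code{\link{helixDefinitions}}.
#' @param reference folded reference structure.
#' @param aprRange aggregation-prone residue range.
#' @param sasaPoints quadrature points for SASA.
#' @return list of class \code{basinReport}.
#' @export
basinReport <- function(structure, label, helices = helixDefinitions(),
                        reference, aprRange = c(42L, 48L),
                        sasaPoints = 240L) {
  nf <- nFrames(structure)
  if (nf < 1L) {
    out <- list(label = label, empty = TRUE)
    class(out) <- "basinReport"
    return(out)
  }
  ss <- ssPopulations(structure)
  rg <- mean(vapply(seq_len(nf), function(f)
    radiusOfGyration(structure, frame = f), numeric(1)))
  sasa <- lapply(seq_len(nf), function(f)
    shrakeRupleySasa(structure, frame = f, nPoints = sasaPoints,
                     aprRange = aprRange))
  out <- list(
    label = label, empty = FALSE, frames = nf,
    helicity = helicityPerHelix(structure, helices, reference),
    ssPopulation = ss$mean,
    rg = rg,
    distanceMatrix = helixDistanceMatrix(structure, helices),
    sasaTotal = mean(vapply(sasa, `[[`, numeric(1), "total")),
    sasaHydrophobic = mean(vapply(sasa, `[[`, numeric(1), "hydrophobic")),
    sasaApr = mean(vapply(sasa, `[[`, numeric(1), "apr")))
  class(out) <- "basinReport"
  out
}

#' @export
print.basinReport <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("Basin %s: empty\n", x$label))
    return(invisible(x))
  }
  cat(sprintf("Basin %s (%d frames)\n", x$label, x$frames))
  cat(sprintf("  helicity (I, II, III): %s\n",
              paste(sprintf("%.2f", x$helicity), collapse = ", ")))
  cat(sprintf("  SS: %.0f%% helix / %.0f%% coil;  Rg = %.2f nm\n",
              100 * x$ssPopulation["helix"], 100 * x$ssPopulation["coil"],
              x$rg))
  cat(sprintf("  SASA total %.1f, hydrophobic %.1f, APR %.2f nm^2\n",
              x$sasaTotal, x$sasaHydrophobic, x$sasaApr))
  invisible(x)
}

#' Secondary-structure populations across a temperature ladder
#'
#' Mean helix and coil fractions (with standard errors over frames) per
#' temperature, sorted by temperature. A folded protein shows a monotone
#' non-increasing helix fraction with temperature.
#'
#' @param frameSets named list: temperature (K, as names or a separate
#'   \code{temperatures} vector) -> multi-frame \code{BackboneStructure}.
#' @param temperatures temperatures matching \code{frameSets}.
#' @return data.frame: temperature, helixFraction, coilFraction, se, n.
#' @export
temperatureSSProfile <- function(frameSets, temperatures = NULL) {
  if (is.null(temperatures)) temperatures <- as.numeric(names(frameSets))
  if (length(frameSets) < 2L) stop("need at least 2 temperatures")
  stopifnot(length(temperatures) == length(frameSets))
  rows <- lapply(seq_along(frameSets), function(k) {
    st <- frameSets[[k]]
    if (is.null(st) || nFrames(st) < 1L) {
      return(data.frame(temperature = temperatures[k],
                        helixFraction = NA_real_, coilFraction = NA_real_,
                        se = NA_real_, n = 0L, flagged = TRUE))
    }
    fr <- ssPopulations(st)$perFrame$helixFraction
    data.frame(temperature = temperatures[k], helixFraction = mean(fr),
               coilFraction = 1 - mean(fr),
               se = if (length(fr) > 1L) sd(fr) / sqrt(length(fr)) else NA_real_,
               n = length(fr), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature), ]
}
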