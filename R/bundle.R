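## Three-helix bundle fixture emulating a folded 76-residue helical fragment:
## helix I residues 1-27, helix II 32-47 (antiparallel), helix III 50-69,
## connecting loops 28-31 and 48-49, C-terminal tail 70-76.

## rotation taking unit vector a onto unit vector b
rotationBetween <- function(a, b) {
  a <- a / vnorm(a); b <- b / vnorm(b)
  v <- crossProduct(a, b); s <- vnorm(v); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- crossProduct(a, p); v <- v / vnorm(v)
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

## CA-fitted helix axis (unit vector from N- to C-terminal end)
helixAxis <- function(ca) {
  cen <- sweep(ca, 2, colMeans(ca))
  ax <- svd(cen)$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
  ax
}

## orient an ideal helix along `direction` with CA centroid at `center`
placeHelix <- function(helix, center, direction) {
  ca <- frameCoords(helix)[helix@atoms$name == "CA", ]
  R <- rotationBetween(helixAxis(ca), direction / vnorm(direction))
  rotated <- transformStructure(helix, rotation = R)
  ca2 <- frameCoords(rotated)[rotated@atoms$name == "CA", ]
  transformStructure(rotated, translation = center - colMeans(ca2))
}

## CA positions for a loop of k residues bridging anchors p0 -> p1 (exclusive),
## zig-zagging perpendicular to the chord when the straight spacing would fall
## below the covalent CA-CA range.
bridgeCAs <- function(p0, p1, k, target = 0.365) {
  gaps <- k + 1L
  chord <- p1 - p0
  L <- vnorm(chord)
  a <- L / gaps
  if (a > 0.55) stop(sprintf("loop of %d residues cannot span %.2f nm", k, L))
  u <- chord / L
  perp <- crossProduct(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
  perp <- perp / vnorm(perp)
  h <- if (a < 0.3) sqrt(max(target^2 - a^2, 0)) else 0
  t(vapply(seq_len(k), function(i) {
    off <- if (h > 0 && i %% 2L == 1L) h / 2 else if (h > 0) -h / 2 else 0
    p0 + u * (a * i) + perp * off
  }, numeric(3)))
}

## attach N, C, O to coil CA positions using local chain tangents; prev/nxt
## are the neighbouring CA positions outside the loop (for end tangents)
coilBackbone <- function(ca, prev, nxt) {
  k <- nrow(ca)
  ext <- rbind(prev, ca, nxt)
  N <- matrix(NA_real_, k, 3); C <- N; O <- N
  for (i in seq_len(k)) {
    tp <- ext[i + 1, ] - ext[i, ]; tp <- tp / vnorm(tp)       # inbound tangent
    tn <- ext[i + 2, ] - ext[i + 1, ]; tn <- tn / vnorm(tn)   # outbound tangent
    up <- crossProduct(tp, tn)
    if (vnorm(up) < 1e-8) up <- crossProduct(tp, if (abs(tp[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
    up <- up / vnorm(up)
    N[i, ] <- ca[i, ] - 0.1458 * (0.94 * tp + 0.34 * up)
    C[i, ] <- ca[i, ] + 0.1525 * (0.94 * tn - 0.34 * up)
    O[i, ] <- C[i, ] + 0.1231 * up
  }
  list(N = N, C = C, O = O)
}

#' Default helix residue ranges of the bundle fixture
#'
#' Helix I: 1-27, helix II: 32-47, helix III: 50-69 (1-based inclusive),
#' matching a 76-residue three-helix fragment.
#'
#' @return named list of integer ranges.
#' @export
defaultHelixRanges <- function() {
  list(I = c(1L, 27L), II = c(32L, 47L), III = c(50L, 69L))
}

#' Build the folded three-helix bundle fixture
#'
#' Constructs a 76-residue single-chain backbone: three ideal alpha-helices
#' (residues 1-27, 32-47 antiparallel, 50-69) packed with pairwise axis
#' separations of about \code{axisSep} nm, connected by short coil loops and
#' a C-terminal coil tail. This is the folded reference used throughout the
#' descriptor, basin and SASA analyses.
#'
#' @param axisSep approximate helix-axis separation, nm.
#' @param seed integer seed (construction is deterministic; kept for
#'   interface uniformity).
#' @return single-frame \code{BackboneStructure} with 76 residues.
#' @export
buildHelixBundle <- function(axisSep = 0.9, seed = 1L) {
  rng <- defaultHelixRanges()
  nres <- 76L
  resnames <- .defaultResnames(nres)
  lenI <- diff(rng$I) + 1L; lenII <- diff(rng$II) + 1L; lenIII <- diff(rng$III) + 1L
  hI <- placeHelix(buildIdealHelix(lenI), c(0, 0, 1.95), c(0, 0, 1))
  hII <- placeHelix(buildIdealHelix(lenII), c(axisSep, 0, 2.5), c(0, 0, -1))
  hIII <- placeHelix(buildIdealHelix(lenIII),
                     c(axisSep / 2, axisSep * sqrt(3) / 2, 2.6), c(0, 0, 1))
  getMat <- function(h, nm) frameCoords(h)[h@atoms$name == nm, , drop = FALSE]
  N <- matrix(NA_real_, nres, 3); CA <- N; C <- N; O <- N
  fill <- function(h, range) {
    idx <- range[1]:range[2]
    N[idx, ] <<- getMat(h, "N"); CA[idx, ] <<- getMat(h, "CA")
    C[idx, ] <<- getMat(h, "C"); O[idx, ] <<- getMat(h, "O")
  }
  fill(hI, rng$I); fill(hII, rng$II); fill(hIII, rng$III)
  buildLoop <- function(from, to, residues) {
    ca <- bridgeCAs(CA[from, ], CA[to, ], length(residues))
    bb <- coilBackbone(ca, CA[from, ], CA[to, ])
    CA[residues, ] <<- ca
    N[residues, ] <<- bb$N; C[residues, ] <<- bb$C; O[residues, ] <<- bb$O
  }
  buildLoop(27L, 32L, 28:31)
  buildLoop(47L, 50L, 48:49)
  # C-terminal tail 70-76: coil leading away from the bundle centre
  centre <- colMeans(CA[c(rng$I[1]:rng$I[2], rng$II[1]:rng$II[2],
                          rng$III[1]:rng$III[2]), ])
  dirOut <- CA[69L, ] - centre
  dirOut[3] <- abs(dirOut[3]) + 0.5
  dirOut <- dirOut / vnorm(dirOut)
  tailIdx <- 70:76
  tailEnd <- CA[69L, ] + dirOut * 0.36 * (length(tailIdx) + 1L)
  ca <- bridgeCAs(CA[69L, ], tailEnd, length(tailIdx))
  bb <- coilBackbone(ca, CA[69L, ], tailEnd)
  CA[tailIdx, ] <- ca; N[tailIdx, ] <- bb$N
  C[tailIdx, ] <- bb$C; O[tailIdx, ] <- bb$O
  assembleBackbone(N, CA, C, O, resnames)
}

#' Core-exposure fixture: helix II displaced outward
#'
#' Returns the folded bundle together with a copy in which helix II
#' (carrying most of the aggregation-prone region) is rigidly displaced away
#' from the bundle axis and its flanking loops re-bridged. The displaced
#' structure exposes the buried APR face while the rest of the fold is
#' untouched — localized core exposure rather than wholesale unfolding.
#'
#' @param offset outward displacement, nm.
#' @return list with \code{folded} and \code{exposed}
#'   \code{BackboneStructure}s.
#' @export
aprExposureFixture <- function(offset = 0.15) {
  b <- buildHelixBundle()
  at <- b@atoms
  xyz <- frameCoords(b)
  caSel <- at$name == "CA"
  centre <- colMeans(xyz[caSel & at$resid <= 69, , drop = FALSE])
  helixII <- colMeans(xyz[caSel & at$resid >= 32 & at$resid <= 47, , drop = FALSE])
  dir <- helixII - centre
  dir[3] <- 0
  dir <- dir / vnorm(dir)
  list(folded = b,
       exposed = displaceSegment(b, c(32L, 47L), offset * dir))
}

#' Rigidly displace a residue segment and re-bridge its flanking loops
#'
#' Translates all backbone atoms of residues in \code{range} by
#' \code{offset} and rebuilds the coil residues in \code{rebridge} (a list of
#' loop residue ranges) between their new anchors, preserving chain
#' connectivity. Used to construct core-exposure fixtures (e.g. helix II
#' moved outward so the aggregation-prone face becomes solvent accessible).
#'
#' @param structure single-frame \code{BackboneStructure}.
#' @param range length-2 integer residue range to displace (inclusive).
#' @param offset length-3 translation, nm.
#' @param rebridge list of loop residue ranges to rebuild.
#' @return displaced \code{BackboneStructure}.
#' @export
displaceSegment <- function(structure, range, offset,
                            rebridge = list(c(28L, 31L), c(48L, 49L))) {
  at <- structure@atoms
  xyz <- frameCoords(structure)
  sel <- at$resid >= range[1] & at$resid <= range[2]
  xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, -offset)
  resn <- at$resname[at$name == "CA"]
  getm <- function(nm) xyz[at$name == nm, , drop = FALSE]
  N <- getm("N"); CA <- getm("CA"); C <- getm("C"); O <- getm("O")
  for (loop in rebridge) {
    residues <- loop[1]:loop[2]
    from <- loop[1] - 1L; to <- loop[2] + 1L
    ca <- bridgeCAs(CA[from, ], CA[to, ], length(residues))
    bb <- coilBackbone(ca, CA[from, ], CA[to, ])
    CA[residues, ] <- ca
    N[residues, ] <- bb$N; C[residues, ] <- bb$C; O[residues, ] <- bb$O
  }
  assembleBackbone(N, CA, C, O, resn)
}
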