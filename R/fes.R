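#' Reweight biased frames to the unbiased ensemble
#'
#' Final-bias (time-independent) reweighting:
#' \eqn{w_i \propto \exp(+V(s_i)/k_BT)}, normalized to sum 1. A max-shift
#' guards the exponentiation against overflow.
#'
#' @param traj \code{CVTrajectory}.
#' @param bias \code{BiasPotential} (NULL gives uniform weights).
#' @param temperature kelvin.
#' @return numeric weight vector summing to 1.
#' @export
reweightFrames <- function(traj, bias = NULL,
                           temperature = traj@temperature) {
  s <- cvValues(traj)
  v <- if (is.null(bias)) numeric(length(s)) else evaluateBias(bias, s)
  logw <- v / kBT(temperature)
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

.binIndex <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  # clip out-of-bounds samples to the edge bins
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Weighted free-energy surface from CV samples
#'
#' Bins samples on a 1D or 2D uniform grid and Boltzmann-inverts the weighted
#' histogram: \eqn{F(bin) = -k_BT \ln \sum_{i \in bin} w_i}, shifted so the
#' minimum over visited bins is zero. Empty bins are masked. Out-of-bounds
#' samples are clipped to edge bins; the clipped count is reported as an
#' attribute.
#'
#' @param samples numeric vector (1D) or 2-column matrix (2D) of CV values.
#' @param weights frame weights (default uniform); need not be normalized.
#' @param edges list of bin-edge vectors, one per axis, or NULL to use
#'   \code{nbins} bins over the sample range padded 5 percent.
#' @param nbins bins per axis when \code{edges} is NULL.
#' @param temperature kelvin.
#' @param cvNames axis names.
#' @return \code{\linkS4class{FESGrid}} in RT units, with attribute
#'   \code{"clipped"} on the values giving the out-of-bounds count.
#' @export
weightedFES <- function(samples, weights = NULL, edges = NULL, nbins = 64L,
                        temperature = 300, cvNames = NULL) {
  m <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1L)
  ndim <- ncol(m)
  stopifnot(ndim %in% 1:2)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0))
  if (is.null(cvNames)) cvNames <- if (ndim == 1L) "s" else c("s1", "s2")
  if (is.null(edges)) {
    edges <- lapply(seq_len(ndim), function(d) {
      r <- range(m[, d])
      pad <- 0.05 * max(diff(r), 1e-12)
      seq(r[1] - pad, r[2] + pad, length.out = nbins + 1L)
    })
  }
  clipped <- 0L
  for (d in seq_len(ndim)) {
    clipped <- clipped + sum(m[, d] < edges[[d]][1] |
                             m[, d] > edges[[d]][length(edges[[d]])])
  }
  idx <- lapply(seq_len(ndim), function(d) .binIndex(m[, d], edges[[d]]))
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  acc <- array(0, dim = dims)
  flat <- if (ndim == 1L) idx[[1]] else (idx[[2]] - 1L) * dims[1] + idx[[1]]
  sums <- tapply(weights, flat, sum)
  acc[as.integer(names(sums))] <- sums
  if (all(acc == 0)) stop("all samples fall outside the grid")
  mask <- acc == 0
  vals <- array(NA_real_, dim = dims)
  vals[!mask] <- -log(acc[!mask])  # in RT; shift applied by constructor
  if (ndim == 1L) { vals <- as.numeric(vals); mask <- as.logical(mask) }
  axes <- lapply(seq_len(ndim), function(d)
    list(name = cvNames[d], edges = edges[[d]]))
  g <- makeFESGrid(axes = axes, values = vals, mask = mask, unit = "RT",
                   temperature = temperature)
  attr(g@values, "clipped") <- clipped
  g
}

#' Time-resolved FES snapshots and convergence metric
#'
#' Rebuilds the well-tempered FES from the bias truncated at each requested
#' time and reports the maximum absolute deviation between consecutive
#' snapshots over unmasked bins — the surface is converged when the late
#' deviations are small (the FES becomes static in time).
#'
#' @param bias \code{BiasPotential} with timestamped depositions.
#' @param gridLo,gridHi,nbins CV grid geometry.
#' @param times increasing vector of snapshot times, ps.
#' @param temperature analysis temperature, K.
#' @return list with \code{surfaces} (list of \code{FESGrid}) and
#'   \code{deviations} (RT, length \code{length(times) - 1}).
#' @export
fesTimeSeries <- function(bias, gridLo, gridHi, nbins = 200L, times,
                          temperature = bias@temperature) {
  if (!length(times)) stop("at least one snapshot time is required")
  surfaces <- lapply(times, function(tm)
    suppressWarnings(fesFromBias(bias, gridLo, gridHi, nbins,
                                 temperature = temperature, tmax = tm)))
  deviations <- if (length(times) > 1L) {
    vapply(seq_len(length(times) - 1L), function(k) {
      a <- fesValues(surfaces[[k]]); b <- fesValues(surfaces[[k + 1L]])
      max(abs(a - b), na.rm = TRUE)
    }, numeric(1))
  } else numeric(0)
  list(surfaces = surfaces, deviations = deviations)
}

#' CV diffusion summary
#'
#' Per-window range and variance of the CV plus the number of crossings of
#' the CV midpoint — enhanced sampling shows larger fluctuations and many
#' more crossings than an unbiased run stuck in one basin.
#'
#' @param traj \code{CVTrajectory}.
#' @param nWindows number of equal time windows.
#' @return list with \code{windows} (data.frame: start, end, range,
#'   variance), \code{midpoint}, \code{crossings}, \code{variance}.
#' @export
cvDiffusionSummary <- function(traj, nWindows = 10L) {
  s <- cvValues(traj)
  if (length(s) < 2L) stop("need at least 2 frames")
  mid <- (min(s) + max(s)) / 2
  crossings <- sum(diff(sign(s - mid)) != 0 & sign(s - mid)[-length(s)] != 0)
  if (min(s) == max(s)) crossings <- 0L
  brk <- floor(seq(0, length(s), length.out = nWindows + 1L))
  windows <- do.call(rbind, lapply(seq_len(nWindows), function(k) {
    sel <- (brk[k] + 1L):brk[k + 1L]
    data.frame(start = sel[1], end = sel[length(sel)],
               range = max(s[sel]) - min(s[sel]),
               variance = if (length(sel) > 1L) var(s[sel]) else 0)
  }))
  list(windows = windows, midpoint = mid, crossings = crossings,
       variance = var(s))
}

#' Write an FES grid as plain text
#'
#' Header lines name the CVs, bin counts, edges, unit and temperature; one
#' row per bin with bin-centre coordinates and the free energy. Masked
#' (never-visited) bins carry the sentinel \code{MASKED}, never a number.
#'
#' @param fes \code{FESGrid}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeFESGrid <- function(fes, file) {
  ax <- fes@axes
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fes ndim %d unit %s temperature %.17g",
                     length(ax), fes@unit, fes@temperature), con)
  for (a in ax) {
    writeLines(sprintf("# axis %s nbins %d edges %s", a$name,
                       length(a$edges) - 1L,
                       paste(sprintf("%.17g", a$edges), collapse = " ")), con)
  }
  v <- fes@values; msk <- fes@mask
  centers <- lapply(ax, function(a) (a$edges[-1] + a$edges[-length(a$edges)]) / 2)
  if (length(ax) == 1L) {
    for (i in seq_along(v)) {
      writeLines(sprintf("%.17g %s", centers[[1]][i],
                         if (msk[i]) "MASKED" else sprintf("%.17g", v[i])), con)
    }
  } else {
    for (j in seq_along(centers[[2]])) for (i in seq_along(centers[[1]])) {
      writeLines(sprintf("%.17g %.17g %s", centers[[1]][i], centers[[2]][j],
                         if (msk[i, j]) "MASKED" else sprintf("%.17g", v[i, j])),
                 con)
    }
  }
  invisible(file)
}

#' Read an FES grid written by \code{\link{writeFESGrid}}
#'
#' @param file path.
#' @return \code{FESGrid}.
#' @export
readFESGrid <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  h1 <- strsplit(hdr[1], "[[:space:]]+")[[1]]
  ndim <- as.integer(h1[4]); unit <- h1[6]; temp <- as.numeric(h1[8])
  axes <- lapply(hdr[-1], function(l) {
    p <- strsplit(l, "[[:space:]]+")[[1]]
    list(name = p[3], edges = as.numeric(p[-(1:6)]))
  })
  dims <- vapply(axes, function(a) length(a$edges) - 1L, integer(1))
  toks <- strsplit(trimws(body), "[[:space:]]+")
  raw <- vapply(toks, function(t) t[length(t)], "")
  vals <- suppressWarnings(as.numeric(ifelse(raw == "MASKED", NA, raw)))
  mask <- raw == "MASKED"
  if (ndim == 2L) {
    vals <- matrix(vals, dims[1], dims[2])
    mask <- matrix(mask, dims[1], dims[2])
  }
  new("FESGrid", axes = axes, values = vals, mask = mask, unit = unit,
      temperature = temp)
}
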