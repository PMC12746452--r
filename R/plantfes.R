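#' Plant a free-energy grid with known minima and saddle heights
#'
#' Realizes a 1D or 2D FES grid in which the listed minima (chain topology:
#' minimum i connects to minimum i+1 through saddle i) are strict local
#' minima at the stated depths and the minimax barrier between any two
#' minima is exactly the maximum of the intervening planted saddles. All
#' off-channel nodes sit above every saddle, so exhaustive search recovers
#' the planted barriers to within grid quantization.
#'
#' @param minima list of \code{list(pos = c(...), depth = RT)}; depths are
#'   free energies (min must be 0 to satisfy the grid convention).
#' @param saddles numeric vector of saddle heights (RT), one fewer than
#'   minima; each must exceed both adjacent depths.
#' @param edges list of bin-edge vectors (one per axis).
#' @param temperature annotation temperature, K.
#' @param rim height of the off-channel plateau; default 2 RT above the
#'   highest saddle.
#' @return object of class \code{plantedFES}: list with \code{fes}
#'   (\code{FESGrid}), \code{nodes} (minima bin indices), \code{depths},
#'   \code{saddles}.
#' @export
plantFES <- function(minima, saddles, edges, temperature = 300, rim = NULL) {
  if (length(minima) < 2L) stop("at least 2 minima are required")
  if (length(saddles) != length(minima) - 1L)
    stop("need exactly one saddle height per adjacent pair of minima")
  ndim <- length(minima[[1]]$pos)
  stopifnot(ndim %in% 1:2, length(edges) == ndim)
  depths <- vapply(minima, `[[`, numeric(1), "depth")
  if (abs(min(depths)) > 1e-12) stop("the deepest minimum must have depth 0")
  for (k in seq_along(saddles)) {
    if (saddles[k] <= max(depths[k], depths[k + 1L]))
      stop("each saddle height must exceed both adjacent minima depths")
  }
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  toNode <- function(pos) {
    vapply(seq_len(ndim), function(d) which.min(abs(centers[[d]] - pos[d])),
           integer(1))
  }
  nodes <- lapply(minima, function(m) toNode(m$pos))
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
    if (a < b && max(abs(nodes[[a]] - nodes[[b]])) < 2L)
      stop("minima closer than 2 grid cells are unresolvable")
  }
  if (is.null(rim)) rim <- max(saddles) + 2

  # 8-connected node chain from a to b (diagonal first, then straight)
  chainNodes <- function(a, b) {
    path <- list(a)
    cur <- a
    while (any(cur != b)) {
      step <- sign(b - cur)
      cur <- cur + step
      path[[length(path) + 1L]] <- cur
    }
    path
  }

  vals <- array(rim, dim = c(dims, 1L))[, , 1L, drop = TRUE]
  if (ndim == 1L) vals <- rep(rim, dims[1]) else vals <- matrix(rim, dims[1], dims[2])
  # gentle off-channel slope away from the first minimum keeps the rim free
  # of plateaus without creating spurious minima
  if (ndim == 1L) {
    dist0 <- abs(seq_len(dims[1]) - nodes[[1]][1])
    vals <- vals + 1e-3 * dist0
  } else {
    dist0 <- outer(abs(seq_len(dims[1]) - nodes[[1]][1]),
                   abs(seq_len(dims[2]) - nodes[[1]][2]), pmax)
    vals <- vals + 1e-3 * dist0
  }
  setVal <- function(node, v) {
    if (ndim == 1L) vals[node[1]] <<- v else vals[node[1], node[2]] <<- v
  }
  getVal <- function(node) {
    if (ndim == 1L) vals[node[1]] else vals[node[1], node[2]]
  }
  for (k in seq_along(saddles)) {
    ch <- chainNodes(nodes[[k]], nodes[[k + 1L]])
    L <- length(ch)
    mid <- (L + 1L) / 2
    prof <- vapply(seq_len(L), function(i) {
      if (i <= mid) {
        depths[k] + (saddles[k] - depths[k]) * (i - 1) / (mid - 1)
      } else {
        saddles[k] + (depths[k + 1L] - saddles[k]) * (i - mid) / (L - mid)
      }
    }, numeric(1))
    # keep the exact saddle at the profile maximum
    prof[ceiling(mid)] <- saddles[k]
    for (i in seq_len(L)) setVal(ch[[i]], min(getVal(ch[[i]]), prof[i]))
  }
  for (k in seq_along(nodes)) setVal(nodes[[k]], depths[k])
  axes <- lapply(seq_len(ndim), function(d)
    list(name = if (ndim == 1L) "s" else c("s1", "s2")[d], edges = edges[[d]]))
  fes <- makeFESGrid(axes = axes, values = vals,
                     mask = if (ndim == 1L) rep(FALSE, dims[1]) else
                       matrix(FALSE, dims[1], dims[2]),
                     unit = "RT", temperature = temperature)
  structure(list(fes = fes, nodes = nodes, depths = depths,
                 saddles = saddles),
            class = "plantedFES")
}
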