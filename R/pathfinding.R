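## Grid helpers shared by the basin/path analyses. Nodes are per-axis bin
## indices; lexicographic order is (i1, then i2); 8-connectivity on 2D grids
## (2-connectivity in 1D), configurable to 4.

.gridDims <- function(fes) {
  vapply(fes@axes, function(a) length(a$edges) - 1L, integer(1))
}

.nodeEnergy <- function(E, node) {
  if (length(node) == 1L) E[node[1]] else E[node[1], node[2]]
}

.neighbors <- function(node, dims, connectivity = 8L) {
  if (length(dims) == 1L) {
    cand <- list(node - 1L, node + 1L)
  } else {
    offs <- expand.grid(di = -1:1, dj = -1:1)
    offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
    if (connectivity == 4L) offs <- offs[abs(offs$di) + abs(offs$dj) == 1, ]
    cand <- lapply(seq_len(nrow(offs)), function(k)
      c(node[1] + offs$di[k], node[2] + offs$dj[k]))
  }
  Filter(function(p) all(p >= 1L) && all(p <= dims), cand)
}

.linIndex <- function(node, dims) {
  if (length(dims) == 1L) node[1] else (node[2] - 1L) * dims[1] + node[1]
}

.nodeFromLin <- function(lin, dims) {
  if (length(dims) == 1L) lin
  else c((lin - 1L) %% dims[1] + 1L, (lin - 1L) %/% dims[1] + 1L)
}

#' Locate free-energy basins on an FES grid
#'
#' Finds strict local minima under the declared neighbourhood (plateaus
#' collapse to their lowest lexicographic node) and prunes shallow basins by
#' topological persistence: a basin whose depth below its lowest escape
#' saddle is less than \code{minDepth} is merged into the neighbouring
#' basin. Labels are assigned 1..K by increasing energy (ties by
#' lexicographic node order). Deterministic: re-running on the same grid is
#' bit-identical.
#'
#' @param fes \code{FESGrid} (1D or 2D).
#' @param minDepth pruning threshold in the grid's energy unit (default 0.5).
#' @param connectivity 8 (default) or 4 (2D grids only).
#' @param maxEnergy report only basins at or below this free energy
#'   (default Inf): sparsely sampled high-energy bins produce statistical
#'   minima that are not metastable states.
#' @return data.frame with one row per basin: \code{label}, node indices
#'   (\code{i1}, \code{i2}), CV coordinates, \code{energy}, and
#'   \code{escape} (lowest saddle level at which the basin merges; Inf for
#'   the global minimum).
#' @export
findMinima <- function(fes, minDepth = 0.5, connectivity = 8L,
                       maxEnergy = Inf) {
  E <- fesValues(fes)
  dims <- .gridDims(fes)
  ndim <- length(dims)
  unmasked <- which(!is.na(E))
  if (!length(unmasked)) stop("all grid bins are masked")
  # process nodes ascending by energy, ties by lexicographic node order
  nodesLin <- unmasked
  lex <- vapply(nodesLin, function(l) {
    nd <- .nodeFromLin(l, dims)
    if (ndim == 1L) nd[1] else (nd[1] - 1) * dims[2] + nd[2]
  }, numeric(1))
  ord <- nodesLin[order(E[nodesLin], lex)]

  parent <- integer(prod(dims))          # 0 = unprocessed
  compMin <- integer(prod(dims))         # root -> linear index of its minimum
  escape <- rep(Inf, prod(dims))         # minimum lin -> merge (saddle) level
  alive <- logical(prod(dims))           # minimum lin -> survived pruning
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (l in ord) {
    nd <- .nodeFromLin(l, dims)
    nbrs <- .neighbors(nd, dims, connectivity)
    roots <- integer(0)
    for (nb in nbrs) {
      nl <- .linIndex(nb, dims)
      if (parent[nl] != 0L) roots <- c(roots, find(nl))
    }
    roots <- unique(roots)
    if (!length(roots)) {
      parent[l] <- l
      compMin[l] <- l
      alive[l] <- TRUE
      next
    }
    # attach to the component whose minimum is lowest (ties: lex)
    mins <- compMin[roots]
    o <- order(E[mins], vapply(mins, function(m) {
      nd2 <- .nodeFromLin(m, dims)
      if (ndim == 1L) nd2[1] else (nd2[1] - 1) * dims[2] + nd2[2]
    }, numeric(1)))
    roots <- roots[o]; mins <- mins[o]
    main <- roots[1]
    parent[l] <- main
    if (length(roots) > 1L) {
      for (k in 2:length(roots)) {
        m <- mins[k]
        pers <- E[l] - E[m]
        escape[m] <- min(escape[m], E[l])
        if (pers < minDepth) alive[m] <- FALSE
        parent[roots[k]] <- main
      }
    }
  }
  minsLin <- which(alive & E[seq_along(alive)] <= maxEnergy &
                   !is.na(E[seq_along(alive)]))
  # drop plateau duplicates: only component-founding nodes are in `alive`;
  # a founder that has an unmasked neighbour with strictly lower energy was
  # attached to it at processing time and never founded a component.
  info <- lapply(minsLin, function(l) {
    nd <- .nodeFromLin(l, dims)
    coords <- vapply(seq_len(ndim), function(d) {
      e <- fes@axes[[d]]$edges
      ((e[-1] + e[-length(e)]) / 2)[nd[d]]
    }, numeric(1))
    list(node = nd, coords = coords, energy = E[l], escape = escape[l])
  })
  o <- order(vapply(info, `[[`, numeric(1), "energy"),
             vapply(info, function(x) {
               nd <- x$node
               if (ndim == 1L) nd[1] else (nd[1] - 1) * dims[2] + nd[2]
             }, numeric(1)))
  info <- info[o]
  out <- data.frame(
    label = seq_along(info),
    i1 = vapply(info, function(x) x$node[1], integer(1)),
    i2 = if (ndim == 2L) vapply(info, function(x) x$node[2], integer(1)) else NA_integer_,
    c1 = vapply(info, function(x) x$coords[1], numeric(1)),
    c2 = if (ndim == 2L) vapply(info, function(x) x$coords[2], numeric(1)) else NA_real_,
    energy = vapply(info, `[[`, numeric(1), "energy"),
    escape = vapply(info, `[[`, numeric(1), "escape"))
  out
}

.basinNode <- function(basins, label) {
  row <- basins[basins$label == label, ]
  if (!nrow(row)) stop(sprintf("no basin with label %d", label))
  if (is.na(row$i2)) row$i1 else c(row$i1, row$i2)
}

#' Minimax (lowest-saddle) path between two basins
#'
#' Among all 8-connected paths across unmasked bins, returns one minimizing
#' the maximum node energy; ties are broken by lower total path energy, then
#' by a deterministic node order. Two stages: the minimax level is found by
#' thresholded connectivity (binary search over node energies), then a
#' Dijkstra run restricted to nodes at or below that level minimizes the
#' energy sum.
#'
#' @param fes \code{FESGrid}.
#' @param basins output of \code{\link{findMinima}}.
#' @param from,to basin labels (source and target; must differ).
#' @param connectivity 8 (default) or 4.
#' @return list of class \code{energyPath}: \code{nodes} (matrix, one row
#'   per node), \code{energies} (path-ordered), \code{pathMax}, and the
#'   \code{unit} of the grid.
#' @export
minimumEnergyPath <- function(fes, basins, from, to, connectivity = 8L) {
  if (from == to) stop("source and target basins must differ")
  E <- fesValues(fes)
  dims <- .gridDims(fes)
  src <- .basinNode(basins, from)
  dst <- .basinNode(basins, to)
  if (is.na(.nodeEnergy(E, src)) || is.na(.nodeEnergy(E, dst)))
    stop("source or target sits on a masked bin")
  srcLin <- .linIndex(src, dims); dstLin <- .linIndex(dst, dims)

  connectedAt <- function(thr) {
    ok <- !is.na(E) & E <= thr
    if (!ok[srcLin] || !ok[dstLin]) return(FALSE)
    seen <- logical(prod(dims))
    queue <- srcLin
    seen[srcLin] <- TRUE
    while (length(queue)) {
      l <- queue[[1]]; queue <- queue[-1]
      if (l == dstLin) return(TRUE)
      for (nb in .neighbors(.nodeFromLin(l, dims), dims, connectivity)) {
        nl <- .linIndex(nb, dims)
        if (ok[nl] && !seen[nl]) { seen[nl] <- TRUE; queue <- c(queue, nl) }
      }
    }
    FALSE
  }
  levels <- sort(unique(E[!is.na(E)]))
  lo <- 1L; hi <- length(levels)
  if (!connectedAt(levels[hi]))
    stop("basins are disconnected: a masked region separates the endpoints")
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connectedAt(levels[mid])) hi <- mid else lo <- mid + 1L
  }
  thr <- levels[lo]

  # Dijkstra on sum of node energies within the admissible set
  ok <- !is.na(E) & E <= thr
  n <- prod(dims)
  dist <- rep(Inf, n); prev <- integer(n); done <- logical(n)
  dist[srcLin] <- E[srcLin]
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) stop("basins are disconnected at the minimax level")
    u <- cand[which.min(dist[cand])]
    if (u == dstLin) break
    done[u] <- TRUE
    for (nb in .neighbors(.nodeFromLin(u, dims), dims, connectivity)) {
      nl <- .linIndex(nb, dims)
      if (!ok[nl] || done[nl]) next
      alt <- dist[u] + E[nl]
      if (alt < dist[nl] - 1e-15 ||
          (abs(alt - dist[nl]) <= 1e-15 && prev[nl] > u)) {
        dist[nl] <- alt
        prev[nl] <- u
      }
    }
  }
  pathLin <- dstLin
  while (pathLin[1] != srcLin) pathLin <- c(prev[pathLin[1]], pathLin)
  nodes <- if (length(dims) == 1L) matrix(pathLin, ncol = 1L) else
    t(vapply(pathLin, function(l) .nodeFromLin(l, dims),
             integer(length(dims))))
  energies <- E[pathLin]
  structure(list(nodes = nodes, energies = energies,
                 pathMax = max(energies), unit = fes@unit),
            class = "energyPath")
}

#' Barriers along an energy path
#'
#' Identifies the basins visited by the path (in traversal order) and, for
#' each consecutive pair, reports the forward barrier: the maximum energy on
#' the connecting sub-path minus the energy of the earlier basin. Also
#' reports which leg carries the global highest barrier.
#'
#' @param path \code{energyPath} from \code{\link{minimumEnergyPath}}.
#' @param basins output of \code{\link{findMinima}}.
#' @return list with \code{legs} (data.frame: fromLabel, toLabel, barrier,
#'   saddle) and \code{highest} (index into legs).
#' @export
barriersAlongPath <- function(path, basins) {
  nodeKey <- function(m) apply(m, 1, paste, collapse = ",")
  bn <- t(vapply(basins$label, function(l) {
    nd <- .basinNode(basins, l)
    if (length(nd) == 1L) c(nd, NA_integer_) else nd
  }, integer(2)))
  pk <- nodeKey(path$nodes)
  bk <- apply(bn[, seq_len(ncol(path$nodes)), drop = FALSE], 1, paste,
              collapse = ",")
  hits <- which(pk %in% bk)
  if (length(hits) < 2L) stop("path visits fewer than 2 basins")
  lab <- basins$label[match(pk[hits], bk)]
  legs <- do.call(rbind, lapply(seq_len(length(hits) - 1L), function(k) {
    seg <- hits[k]:hits[k + 1L]
    saddle <- max(path$energies[seg])
    data.frame(fromLabel = lab[k], toLabel = lab[k + 1L],
               barrier = saddle - path$energies[hits[k]], saddle = saddle)
  }))
  list(legs = legs, highest = which.max(legs$barrier))
}

#' Assign CV samples to basins
#'
#' A frame joins basin k when its bin lies within \code{radius} bins
#' (Chebyshev) of the basin node and the bin's energy is below the basin's
#' lowest escape saddle. Frames matching several basins go to the nearest
#' node (ties to the lower label); frames on masked bins or matching no
#' basin are reported unassigned.
#'
#' @param samples CV values: vector (1D) or 2-column matrix (2D).
#' @param basins output of \code{\link{findMinima}}.
#' @param fes the grid the basins came from.
#' @param radius Chebyshev radius in bins.
#' @return list with per-basin integer frame-index vectors (named by label)
#'   and \code{unassigned}.
#' @export
assignFramesToBasins <- function(samples, basins, fes, radius = 3L) {
  E <- fesValues(fes)
  dims <- .gridDims(fes)
  ndim <- length(dims)
  m <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1L)
  stopifnot(ncol(m) == ndim)
  idx <- vapply(seq_len(ndim), function(d)
    .binIndex(m[, d], fes@axes[[d]]$edges), integer(nrow(m)))
  if (nrow(m) == 1L) idx <- matrix(idx, 1L)
  nodes <- lapply(basins$label, function(l) .basinNode(basins, l))
  assign <- rep(NA_integer_, nrow(m))
  for (f in seq_len(nrow(m))) {
    bin <- idx[f, ]
    e <- .nodeEnergy(E, bin)
    if (is.na(e)) next
    dcheb <- vapply(nodes, function(nd) max(abs(nd - bin)), integer(1))
    okB <- which(dcheb <= radius & e < basins$escape)
    if (!length(okB)) next
    best <- okB[order(dcheb[okB], basins$label[okB])][1]
    assign[f] <- basins$label[best]
  }
  out <- lapply(basins$label, function(l) which(assign == l))
  names(out) <- as.character(basins$label)
  c(out, list(unassigned = which(is.na(assign))))
}
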