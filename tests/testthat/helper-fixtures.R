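## Shared fixtures (memoized: geometry construction is deterministic) and
## independent brute-force oracles used against the package implementations.

.fx <- new.env()

idealHelix30 <- function() {
  if (is.null(.fx$h30)) .fx$h30 <- buildIdealHelix(30L)
  .fx$h30
}

extendedChain30 <- function() {
  if (is.null(.fx$e30)) .fx$e30 <- meltHelix(idealHelix30(), 1)
  .fx$e30
}

foldedBundle <- function() {
  if (is.null(.fx$bundle)) .fx$bundle <- buildHelixBundle()
  .fx$bundle
}

randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

randomSPD <- function(d) {
  A <- matrix(rnorm(d * d), d)
  A %*% t(A) + diag(d) * 0.1
}

## Exhaustive minimax oracle: enumerate every simple 8-connected path on a
## small grid and return the minimal achievable path maximum.
bruteForceMinimax <- function(E, src, dst) {
  dims <- dim(E)
  neigh <- function(node) {
    out <- list()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      p <- node + c(di, dj)
      if (all(p >= 1) && p[1] <= dims[1] && p[2] <= dims[2])
        out[[length(out) + 1L]] <- p
    }
    out
  }
  best <- Inf
  visited <- matrix(FALSE, dims[1], dims[2])
  dfs <- function(node, curMax) {
    curMax <- max(curMax, E[node[1], node[2]])
    if (curMax >= best) return(invisible())
    if (all(node == dst)) {
      best <<- min(best, curMax)
      return(invisible())
    }
    visited[node[1], node[2]] <<- TRUE
    for (p in neigh(node)) {
      if (!visited[p[1], p[2]]) dfs(p, curMax)
    }
    visited[node[1], node[2]] <<- FALSE
    invisible()
  }
  dfs(src, -Inf)
  best
}

## Wrap a plain matrix as a 2D FESGrid (unit RT, unmasked)
matrixFES <- function(E, temperature = 300) {
  E <- E - min(E)
  d <- dim(E)
  foldscape:::makeFESGrid(
    axes = list(list(name = "s1", edges = seq(0, d[1], by = 1)),
                list(name = "s2", edges = seq(0, d[2], by = 1))),
    values = E, mask = matrix(FALSE, d[1], d[2]), unit = "RT",
    temperature = temperature)
}
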