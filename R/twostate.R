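#' Specification of a labelled two-state descriptor ensemble
#'
#' Defines two six-dimensional Gaussians (folded state A, unfolded state B)
#' from which labelled descriptor samples are drawn, the ground truth for
#' testing discriminant recovery.
#'
#' @param muA,muB mean 6-vectors (descriptor units).
#' @param sigmaA,sigmaB 6x6 symmetric positive-definite covariances.
#' @param nA,nB sample counts (>= 2).
#' @param seed integer seed.
#' @return a \code{twoStateSpec} list, validated.
#' @export
twoStateSpec <- function(muA, muB, sigmaA, sigmaB, nA = 1000L, nB = 1000L,
                         seed = 1L) {
  stopifnot(length(muA) == length(muB))
  checkSPD <- function(S, nm) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop(sprintf("covariance %s is not symmetric", nm))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf("covariance %s is not positive definite (min eigenvalue %g)",
                   nm, min(ev)))
    S
  }
  if (nA < 2 || nB < 2) stop("nA and nB must be >= 2")
  structure(list(muA = as.numeric(muA), muB = as.numeric(muB),
                 sigmaA = checkSPD(sigmaA, "sigmaA"),
                 sigmaB = checkSPD(sigmaB, "sigmaB"),
                 nA = as.integer(nA), nB = as.integer(nB),
                 seed = as.integer(seed)),
            class = "twoStateSpec")
}

## Cholesky-based multivariate normal draw (deterministic per RNG state)
rmvn <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  z <- matrix(rnorm(n * length(mu)), n, length(mu))
  sweep(z %*% L, 2, -mu)
}

#' Draw a labelled two-state descriptor ensemble
#'
#' Samples \code{nA} class-A and \code{nB} class-B descriptor vectors from
#' the two planted Gaussians; sample means converge to the planted means at
#' the usual n^(-1/2) rate. Bit-reproducible under a fixed seed.
#'
#' @param spec a \code{\link{twoStateSpec}}.
#' @return \code{\linkS4class{DescriptorSeries}} with labels
#'   \code{"A"}/\code{"B"} (folded/unfolded).
#' @export
sampleTwoStateDescriptors <- function(spec) {
  stopifnot(inherits(spec, "twoStateSpec"))
  withSeed(spec$seed, {
    a <- rmvn(spec$nA, spec$muA, spec$sigmaA)
    b <- rmvn(spec$nB, spec$muB, spec$sigmaB)
    DescriptorSeries(rbind(a, b),
                     label = c(rep("A", spec$nA), rep("B", spec$nB)))
  })
}

#' Planted HLDA direction of a two-state spec
#'
#' The ground-truth discriminant S_w^{-1} (muA - muB) with S_w the harmonic
#' mean of the planted covariances, unit-normalized.
#'
#' @param spec a \code{\link{twoStateSpec}}.
#' @return unit 6-vector.
#' @export
plantedDirection <- function(spec) {
  # S_w^{-1} dmu with S_w the harmonic mean: (SigmaA^-1 + SigmaB^-1) dmu
  w <- (solve(spec$sigmaA) + solve(spec$sigmaB)) %*% (spec$muA - spec$muB)
  as.numeric(w / vnorm(w))
}
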