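#' @useDynLib foldscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cov optim rnorm runif sd uniroot var integrate
#' @importFrom utils head tail write.table read.table
NULL

## Boltzmann constant in kJ/mol/K (CODATA); all energies kJ/mol, lengths nm,
## times ps, temperatures K unless a function documents otherwise.
.kB <- 0.008314462618

#' Thermal energy k_B T
#'
#' @param temperature Temperature in kelvin.
#' @return k_B T in kJ/mol.
#' @export
kBT <- function(temperature) .kB * temperature

#' Derive a stage- or stream-specific seed from a global seed
#'
#' Counter-based fan-out so independent random streams (replicas, pipeline
#' stages, exchange decisions) are decorrelated but fully determined by one
#' global seed. Always returns an integer in [1, 2^31 - 2].
#'
#' @param seed Global integer seed.
#' @param ... One or more integer counters (stage index, replica index, ...).
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(seed) %% m
  for (k in as.numeric(c(...))) {
    # LCG-style mixing (Park-Miller multiplier); doubles hold these exactly
    x <- (x * 48271 + k + 1) %% m
    x <- (x * 16807 + 12345) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

## Evaluate a function with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

crossProduct <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
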