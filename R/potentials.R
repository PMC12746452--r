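## Analytic toy potentials. Parameter vectors use a fixed positional order
## shared with the compiled propagator:
##   harmonic:         k, x0
##   double-well-1d:   a, b, L         U = a ((x/L)^2-1)^2 + b (x/L)
##   flat-1d:          lo, hi, kwall   U = 0 inside, harmonic walls outside
##   double-funnel-2d: x1,y1,d1,w1, x2,y2,d2,w2, kc
.formId <- c("harmonic" = 1L, "double-well-1d" = 2L, "flat-1d" = 3L,
             "double-funnel-2d" = 4L)

#' Construct an analytic toy potential
#'
#' @param form one of \code{"harmonic"}, \code{"double-well-1d"},
#'   \code{"flat-1d"}, \code{"double-funnel-2d"}.
#' @param ... named parameters (see Details).
#' @details
#' \code{harmonic}: \code{k} (kJ/mol/nm^2), \code{x0} (nm).
#' \code{double-well-1d}: \code{a} (kJ/mol), tilt \code{b} (kJ/mol per
#'   reduced unit) and length scale \code{L} (nm): wells near x = -L and
#'   x = +L. The default L = 0.15 nm puts the basin width on the scale of
#'   the biasing Gaussians, as a discriminant CV's basins are.
#' \code{flat-1d}: zero inside \code{[lo, hi]}, harmonic walls of stiffness
#'   \code{kwall} outside.
#' \code{double-funnel-2d}: two Gaussian wells of depth \code{d1}, \code{d2}
#'   (kJ/mol) and width \code{w1}, \code{w2} (nm) at \code{(x1, y1)},
#'   \code{(x2, y2)}, plus harmonic confinement \code{kc}.
#' @return \code{\linkS4class{ToyPotential}}.
#' @export
toyPotential <- function(form = c("harmonic", "double-well-1d", "flat-1d",
                                  "double-funnel-2d"), ...) {
  form <- match.arg(form)
  given <- list(...)
  defaults <- switch(form,
    "harmonic" = c(k = 10, x0 = 0),
    "double-well-1d" = c(a = 5, b = 0, L = 0.15),
    "flat-1d" = c(lo = -1, hi = 1, kwall = 500),
    "double-funnel-2d" = c(x1 = -0.12, y1 = 0, d1 = 18, w1 = 0.045,
                           x2 = 0.12, y2 = 0.03, d2 = 15, w2 = 0.045,
                           kc = 1000))
  p <- defaults
  if (length(given)) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad)) stop(sprintf("unknown parameter(s) %s for form '%s'",
                                  paste(bad, collapse = ", "), form))
    p[names(given)] <- unlist(given)
  }
  new("ToyPotential", form = form, params = p,
      dim = if (form == "double-funnel-2d") 2L else 1L)
}

#' Potential energy at one or more points
#'
#' @param potential \code{ToyPotential}.
#' @param x numeric vector (1D: points; 2D: a single c(x, y)) or a matrix
#'   with one point per row.
#' @return numeric vector of energies, kJ/mol.
#' @export
potentialEnergy <- function(potential, x) {
  p <- potential@params
  if (potential@dim == 1L) {
    x <- as.numeric(x)
    switch(potential@form,
      "harmonic" = 0.5 * p["k"] * (x - p["x0"])^2,
      "double-well-1d" = p["a"] * ((x / p["L"])^2 - 1)^2 +
        p["b"] * (x / p["L"]),
      "flat-1d" = ifelse(x < p["lo"], 0.5 * p["kwall"] * (x - p["lo"])^2,
                  ifelse(x > p["hi"], 0.5 * p["kwall"] * (x - p["hi"])^2, 0)),
      stop("1D energy undefined for this form")) |> unname()
  } else {
    m <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
    g1 <- exp(-((m[, 1] - p["x1"])^2 + (m[, 2] - p["y1"])^2) / (2 * p["w1"]^2))
    g2 <- exp(-((m[, 1] - p["x2"])^2 + (m[, 2] - p["y2"])^2) / (2 * p["w2"]^2))
    unname(-p["d1"] * g1 - p["d2"] * g2 +
           0.5 * p["kc"] * (m[, 1]^2 + m[, 2]^2))
  }
}

#' Analytic gradient of a toy potential
#'
#' @param potential \code{ToyPotential}.
#' @param x a single point (length 1 or 2).
#' @return gradient vector, kJ/mol/nm.
#' @export
potentialGradient <- function(potential, x) {
  p <- potential@params
  if (potential@dim == 1L) {
    x <- as.numeric(x)[1]
    unname(switch(potential@form,
      "harmonic" = p["k"] * (x - p["x0"]),
      "double-well-1d" = {
        u <- x / p["L"]
        (4 * p["a"] * u * (u^2 - 1) + p["b"]) / p["L"]
      },
      "flat-1d" = if (x < p["lo"]) p["kwall"] * (x - p["lo"])
                  else if (x > p["hi"]) p["kwall"] * (x - p["hi"]) else 0))
  } else {
    g1 <- exp(-((x[1] - p["x1"])^2 + (x[2] - p["y1"])^2) / (2 * p["w1"]^2))
    g2 <- exp(-((x[1] - p["x2"])^2 + (x[2] - p["y2"])^2) / (2 * p["w2"]^2))
    unname(c(
      p["d1"] * g1 * (x[1] - p["x1"]) / p["w1"]^2 +
        p["d2"] * g2 * (x[1] - p["x2"]) / p["w2"]^2 + p["kc"] * x[1],
      p["d1"] * g1 * (x[2] - p["y1"]) / p["w1"]^2 +
        p["d2"] * g2 * (x[2] - p["y2"]) / p["w2"]^2 + p["kc"] * x[2]))
  }
}

#' Exact free-energy difference between the two wells of a 1D potential
#'
#' Computes \eqn{\Delta F = F_{right} - F_{left} =
#' -k_BT \ln(Z_{right}/Z_{left})} by numerical quadrature of the Boltzmann
#' weight on either side of \code{split}. This is the planted ground truth
#' against which sampled and metadynamics estimates are compared.
#'
#' @param potential 1D \code{ToyPotential}.
#' @param temperature kelvin.
#' @param split dividing point between the wells (nm).
#' @param domain integration domain, length 2.
#' @return free-energy difference in kJ/mol (positive when the right well is
#'   higher in free energy).
#' @export
wellFreeEnergyDifference <- function(potential, temperature, split = 0,
                                     domain = NULL) {
  stopifnot(potential@dim == 1L)
  if (is.null(domain)) {
    domain <- if (potential@form == "double-well-1d")
      unname(potential@params["L"]) * c(-4, 4) else c(-3, 3)
  }
  beta <- 1 / kBT(temperature)
  u0 <- min(potentialEnergy(potential, seq(domain[1], domain[2], length.out = 2001)))
  w <- function(x) exp(-beta * (potentialEnergy(potential, x) - u0))
  zl <- integrate(w, domain[1], split, rel.tol = 1e-10)$value
  zr <- integrate(w, split, domain[2], rel.tol = 1e-10)$value
  -kBT(temperature) * log(zr / zl)
}

#' Construct a tilted double well with a prescribed free-energy difference
#'
#' Calibrates the tilt of \code{double-well-1d} by root finding so that the
#' exact (quadrature) free-energy difference between the two wells equals
#' \code{deltaF_kT} thermal units at \code{temperature}. The right-hand well
#' (x near +1) is the deeper, lower-free-energy well when
#' \code{deltaF_kT > 0} is interpreted as F(left) - F(right).
#'
#' @param deltaF_kT target free-energy difference between wells, in k_BT.
#' @param barrier quartic coefficient \code{a} (kJ/mol); the unbiased barrier
#'   height from the wells is approximately \code{a}.
#' @param temperature kelvin.
#' @return list with the \code{potential}, the realized \code{deltaF_kT}
#'   (quadrature) and the tilt \code{b}.
#' @export
makeDoubleWell <- function(deltaF_kT = 3, barrier = 8, temperature = 300) {
  target <- -deltaF_kT * kBT(temperature)  # F_right - F_left, kJ/mol
  f <- function(b) {
    pot <- toyPotential("double-well-1d", a = barrier, b = b)
    wellFreeEnergyDifference(pot, temperature) - target
  }
  b <- uniroot(f, c(-3 * abs(target) - 1e-6, 3 * abs(target) + 1e-6),
               tol = 1e-12)$root
  pot <- toyPotential("double-well-1d", a = barrier, b = b)
  list(potential = pot,
       deltaF_kT = -wellFreeEnergyDifference(pot, temperature) / kBT(temperature),
       b = b)
}
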