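#' Backbone structure: one or more frames of N, CA, C, O coordinates
#'
#' The central coordinate container. Coordinates are stored as an
#' \code{n_atoms x 3 x n_frames} array in nanometres; the atom table records
#' 1-based residue index, 3-letter residue name, atom name (N, CA, C, O) and
#' element. Residue indices are strictly increasing and every residue carries
#' all four backbone atoms.
#'
#' @slot coords numeric array, \code{n_atoms x 3 x n_frames}, nm.
#' @slot atoms data.frame with columns \code{resid}, \code{resname},
#'   \code{name}, \code{element}.
#' @aliases BackboneStructure
#' @export
setClass("BackboneStructure",
  representation(coords = "array", atoms = "data.frame"))

setValidity("BackboneStructure", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("resid", "resname", "name", "element")
  if (!all(need %in% names(a))) {
    return(sprintf("atom table must have columns %s", paste(need, collapse = ", ")))
  }
  if (length(dim(object@coords)) != 3L || dim(object@coords)[2] != 3L) {
    return("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(object@coords)[1] != nrow(a)) {
    return("coords and atom table disagree on atom count")
  }
  resids <- unique(a$resid)
  if (is.unsorted(resids, strictly = TRUE)) msgs <- c(msgs, "residue indices must be strictly increasing")
  per <- split(a$name, a$resid)
  ok <- vapply(per, function(x) all(c("N", "CA", "C", "O") %in% x), logical(1))
  if (!all(ok)) msgs <- c(msgs, sprintf("residue %s missing backbone atoms",
                                        names(per)[which(!ok)[1]]))
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BackboneStructure number of frames (models)
#' @param x A \code{BackboneStructure}.
#' @export
nFrames <- function(x) dim(x@coords)[3]

#' @describeIn BackboneStructure number of residues
#' @export
nResidues <- function(x) length(unique(x@atoms$resid))

#' Extract one frame's coordinate matrix
#'
#' @param x A \code{BackboneStructure}.
#' @param i Frame index.
#' @return \code{n_atoms x 3} matrix (nm).
#' @export
frameCoords <- function(x, i = 1L) {
  stopifnot(i >= 1L, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(x@coords)[1:2]
  m
}

#' @describeIn BackboneStructure atom metadata table
#' @export
atomTable <- function(x) x@atoms

setMethod("show", "BackboneStructure", function(object) {
  cat(sprintf("BackboneStructure: %d residues, %d atoms, %d frame(s)\n",
              nResidues(object), nrow(object@atoms), nFrames(object)))
})

#' Analytic toy potential
#'
#' A low-dimensional analytic potential with evaluable energy and gradient,
#' standing in for a molecular force field when exercising the sampling and
#' biasing machinery. Supported forms: \code{"harmonic"} (1D),
#' \code{"double-well-1d"}, \code{"flat-1d"} (soft walls) and
#' \code{"double-funnel-2d"}.
#'
#' @slot form character form identifier.
#' @slot params named numeric parameter vector (kJ/mol, nm).
#' @slot dim integer dimensionality (1 or 2).
#' @aliases ToyPotential
#' @export
setClass("ToyPotential",
  representation(form = "character", params = "numeric", dim = "integer"))

setValidity("ToyPotential", function(object) {
  if (!object@form %in% c("harmonic", "double-well-1d", "flat-1d", "double-funnel-2d"))
    return(sprintf("unknown potential form '%s'", object@form))
  if (!object@dim %in% c(1L, 2L)) return("dim must be 1 or 2")
  TRUE
})

setMethod("show", "ToyPotential", function(object) {
  cat(sprintf("ToyPotential '%s' (%dD): %s\n", object@form, object@dim,
              paste(sprintf("%s=%g", names(object@params), object@params),
                    collapse = ", ")))
})

#' Six-dimensional descriptor series
#'
#' Ordered frames of the descriptor vector d(R): d1-d3 are per-helix alpha-RMSD
#' counts, d4-d6 switching-transformed helix centre-of-mass distances. May
#' carry class labels (folded/unfolded), time stamps (ps) and the radius of
#' gyration per frame.
#'
#' @slot values numeric matrix, frames x 6, columns d1..d6.
#' @slot time numeric vector of time stamps (ps), possibly empty.
#' @slot label character vector of class labels, possibly empty.
#' @slot rg numeric vector of radii of gyration (nm), possibly empty.
#' @aliases DescriptorSeries
#' @export
setClass("DescriptorSeries",
  representation(values = "matrix", time = "numeric", label = "character",
                 rg = "numeric"))

setValidity("DescriptorSeries", function(object) {
  if (ncol(object@values) != 6L) return("descriptor matrix must have 6 columns")
  n <- nrow(object@values)
  if (length(object@label) && length(object@label) != n)
    return("labels, if present, must cover every frame")
  if (length(object@time) && length(object@time) != n)
    return("time stamps, if present, must cover every frame")
  if (length(object@rg) && length(object@rg) != n)
    return("rg, if present, must cover every frame")
  TRUE
})

#' Construct a DescriptorSeries
#' @param values frames x 6 numeric matrix.
#' @param time,label,rg optional per-frame annotations.
#' @export
DescriptorSeries <- function(values, time = numeric(), label = character(),
                             rg = numeric()) {
  values <- as.matrix(values)
  colnames(values) <- paste0("d", 1:6)
  new("DescriptorSeries", values = values, time = as.numeric(time),
      label = as.character(label), rg = as.numeric(rg))
}

#' @describeIn DescriptorSeries descriptor value matrix
#' @param x A \code{DescriptorSeries}.
#' @export
descriptorValues <- function(x) x@values

#' @describeIn DescriptorSeries per-frame class labels
#' @export
frameLabels <- function(x) x@label

setMethod("show", "DescriptorSeries", function(object) {
  cat(sprintf("DescriptorSeries: %d frame(s)%s\n", nrow(object@values),
              if (length(object@label))
                sprintf(" [labels: %s]", paste(unique(object@label), collapse = ", "))
              else ""))
})

setMethod("length", "DescriptorSeries", function(x) nrow(x@values))

#' Fitted HLDA model
#'
#' Harmonic linear discriminant analysis: the leading generalized eigenvector
#' of S_w^{-1} S_b where S_b is the between-class scatter of the folded and
#' unfolded descriptor means and S_w the harmonic mean of the two class
#' covariances. The weight vector is unit-norm with the sign fixed so its
#' largest-magnitude component is negative.
#'
#' @slot weights unit-norm 6-vector W*.
#' @slot eigenvalues full spectrum, sorted non-increasing.
#' @slot eigenvectors matrix of eigenvectors (columns), same order.
#' @slot separation the discriminant objective J(W*) = dmu' S_w^{-1} dmu.
#' @slot descriptorNames descriptor ordering metadata.
#' @slot degenerate TRUE when the class means coincide (no direction).
#' @aliases HLDAModel
#' @export
setClass("HLDAModel",
  representation(weights = "numeric", eigenvalues = "numeric",
                 eigenvectors = "matrix", separation = "numeric",
                 descriptorNames = "character", degenerate = "logical"))

setValidity("HLDAModel", function(object) {
  if (object@degenerate) return(TRUE)
  # fitted models are unit-norm to 1e-10; parsed interchange weights may carry
  # the precision of their source, so the class tolerates printed rounding
  if (abs(vnorm(object@weights) - 1) > 1e-3) return("weights must be unit norm")
  if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be sorted non-increasing")
  TRUE
})

setMethod("show", "HLDAModel", function(object) {
  if (object@degenerate) {
    cat("HLDAModel: degenerate (class means coincide)\n")
  } else {
    cat("HLDAModel\n  weights:", sprintf("%.3f", object@weights), "\n")
    cat(sprintf("  leading eigenvalue: %.6g  (J = %.6g)\n",
                object@eigenvalues[1], object@separation))
  }
})

#' Metadynamics bias potential
#'
#' The accumulated sum of deposited Gaussians
#' V(s) = sum_i h_i exp(-(s - c_i)^2 / (2 sigma^2)); under well-tempering the
#' deposited height decays as exp(-V(c)/(k_B DeltaT)) with
#' DeltaT = (gamma - 1) T.
#'
#' @slot centers,heights,times deposited Gaussian log (heights kJ/mol).
#' @slot sigma Gaussian width (CV units).
#' @slot gamma bias factor (> 1, may be Inf for standard metadynamics).
#' @slot temperature simulation temperature (K).
#' @aliases BiasPotential
#' @export
setClass("BiasPotential",
  representation(centers = "numeric", heights = "numeric", times = "numeric",
                 sigma = "numeric", gamma = "numeric", temperature = "numeric"))

setValidity("BiasPotential", function(object) {
  if (object@sigma <= 0) return("sigma must be positive")
  if (object@gamma <= 1) return("bias factor gamma must exceed 1")
  if (length(object@heights) && any(object@heights <= 0))
    return("all deposited heights must be positive")
  if (length(object@centers) != length(object@heights))
    return("centers and heights must align")
  TRUE
})

#' Construct an empty BiasPotential
#' @param sigma Gaussian width (CV units).
#' @param gamma bias factor.
#' @param temperature temperature in K.
#' @export
BiasPotential <- function(sigma = 0.02, gamma = 8, temperature = 300) {
  new("BiasPotential", centers = numeric(), heights = numeric(),
      times = numeric(), sigma = sigma, gamma = gamma,
      temperature = temperature)
}

setMethod("show", "BiasPotential", function(object) {
  cat(sprintf("BiasPotential: %d Gaussian(s), sigma=%g, gamma=%g, T=%g K\n",
              length(object@centers), object@sigma, object@gamma,
              object@temperature))
})

#' Collective-variable trajectory
#'
#' Per-step record of a Langevin or metadynamics run: time (ps), one or two
#' coordinates, the collective variable, instantaneous potential energy and
#' bias (kJ/mol), and the replica temperature (K).
#'
#' @slot data numeric matrix with columns \code{time}, coordinate column(s),
#'   \code{cv}, \code{energy}, \code{bias}.
#' @slot temperature replica temperature (K).
#' @aliases CVTrajectory
#' @export
setClass("CVTrajectory",
  representation(data = "matrix", temperature = "numeric"))

setValidity("CVTrajectory", function(object) {
  need <- c("time", "cv", "energy", "bias")
  if (!all(need %in% colnames(object@data)))
    return("trajectory must carry time, cv, energy and bias columns")
  if (any(!is.finite(object@data))) return("trajectory values must be finite")
  TRUE
})

#' @describeIn CVTrajectory the CV value series
#' @param x A \code{CVTrajectory}.
#' @export
cvValues <- function(x) x@data[, "cv"]

#' @describeIn CVTrajectory the full per-step record
#' @export
trajectoryData <- function(x) x@data

setMethod("show", "CVTrajectory", function(object) {
  cat(sprintf("CVTrajectory: %d steps at T=%g K, CV range [%.3g, %.3g]\n",
              nrow(object@data), object@temperature,
              min(object@data[, "cv"]), max(object@data[, "cv"])))
})

#' Free-energy surface on a uniform grid
#'
#' One- or two-dimensional binned free-energy surface with named CV axes.
#' The minimum over unmasked bins is zero; never-visited bins are masked
#' (NA internally, an explicit sentinel in files).
#'
#' @slot axes list of axes; each a list with \code{name} and \code{edges}.
#' @slot values numeric vector (1D) or matrix (2D) of free energies.
#' @slot mask logical same shape; TRUE = masked (never visited).
#' @slot unit \code{"RT"} or \code{"kJ/mol"}.
#' @slot temperature annotation temperature (K).
#' @aliases FESGrid
#' @export
setClass("FESGrid",
  representation(axes = "list", values = "ANY", mask = "ANY",
                 unit = "character", temperature = "numeric"))

setValidity("FESGrid", function(object) {
  if (!length(object@axes) %in% 1:2) return("FESGrid must be 1D or 2D")
  if (!object@unit %in% c("RT", "kJ/mol")) return("unit must be RT or kJ/mol")
  v <- object@values[!object@mask]
  if (length(v)) {
    if (any(!is.finite(v))) return("unmasked bins must be finite")
    if (abs(min(v)) > 1e-9) return("minimum over unmasked bins must be 0")
  }
  if (any(!is.na(object@values[object@mask])))
    return("masked bins must be NA internally")
  TRUE
})

#' @describeIn FESGrid free-energy values (masked bins NA)
#' @param x A \code{FESGrid}.
#' @export
fesValues <- function(x) {
  v <- x@values
  v[x@mask] <- NA_real_
  attr(v, "clipped") <- NULL
  v
}

#' @describeIn FESGrid bin-centre coordinates per axis
#' @export
fesAxes <- function(x) {
  lapply(x@axes, function(a) {
    e <- a$edges
    list(name = a$name, centers = (e[-1] + e[-length(e)]) / 2, edges = e)
  })
}

setMethod("show", "FESGrid", function(object) {
  dims <- vapply(object@axes, function(a) length(a$edges) - 1L, integer(1))
  cat(sprintf("FESGrid (%s): %s bins on (%s), T=%g K, %d masked\n",
              object@unit, paste(dims, collapse = " x "),
              paste(vapply(object@axes, `[[`, "", "name"), collapse = ", "),
              object@temperature, sum(object@mask)))
})

## internal constructor enforcing the zero-minimum convention
makeFESGrid <- function(axes, values, mask, unit, temperature) {
  values[mask] <- NA_real_
  if (any(!mask)) values[!mask] <- values[!mask] - min(values[!mask])
  new("FESGrid", axes = axes, values = values, mask = mask, unit = unit,
      temperature = temperature)
}

#' Replica temperature ladder
#'
#' @slot temperatures strictly increasing temperatures (K).
#' @slot attempts,accepts per adjacent pair exchange counters.
#' @aliases ReplicaLadder
#' @export
setClass("ReplicaLadder",
  representation(temperatures = "numeric", attempts = "numeric",
                 accepts = "numeric"))

setValidity("ReplicaLadder", function(object) {
  if (length(object@temperatures) < 2) return("ladder needs >= 2 replicas")
  if (is.unsorted(object@temperatures, strictly = TRUE))
    return("temperatures must be strictly increasing")
  if (any(object@accepts > object@attempts))
    return("acceptance counts cannot exceed attempts")
  TRUE
})

#' @describeIn ReplicaLadder the temperatures (K)
#' @param x A \code{ReplicaLadder}.
#' @export
ladderTemperatures <- function(x) x@temperatures

setMethod("show", "ReplicaLadder", function(object) {
  cat(sprintf("ReplicaLadder: %d replicas, %g-%g K\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures)))
})
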