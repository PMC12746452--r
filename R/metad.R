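#' Well-tempered metadynamics parameters
#'
#' Defaults follow the biasing protocol used throughout the package's
#' analyses: initial Gaussian height 3.0 kJ/mol, width 0.02 (CV units), bias
#' factor 8, deposition every 100 steps.
#'
#' @param height initial Gaussian height w, kJ/mol (> 0).
#' @param sigma Gaussian width, CV units (> 0).
#' @param gamma bias factor (> 1; \code{Inf} gives standard metadynamics).
#' @param pace deposition pace in steps (>= 1).
#' @param temperature simulation temperature, K.
#' @return validated parameter list of class \code{metadParams}.
#' @export
metadParams <- function(height = 3.0, sigma = 0.02, gamma = 8, pace = 100L,
                        temperature = 300) {
  if (height <= 0) stop("Gaussian height must be positive")
  if (sigma <= 0) stop("Gaussian width must be positive")
  if (gamma <= 1) stop("bias factor gamma must exceed 1")
  if (pace < 1) stop("deposition pace must be >= 1")
  structure(list(height = height, sigma = sigma, gamma = gamma,
                 pace = as.integer(pace), temperature = temperature),
            class = "metadParams")
}

#' Evaluate the accumulated bias potential
#'
#' V(s) = sum_i h_i exp(-(s - c_i)^2 / (2 sigma^2)), with Gaussians truncated
#' at 6 sigma from their centre (relative error < 1e-7 of the height).
#'
#' @param bias \code{BiasPotential}.
#' @param s numeric vector of CV values.
#' @param tmax only Gaussians deposited at or before \code{tmax} (ps) are
#'   included (for time-resolved FES snapshots).
#' @return numeric vector V(s), kJ/mol.
#' @export
evaluateBias <- function(bias, s, tmax = Inf) {
  # untimed depositions (NA) are always part of the bias
  keep <- which(is.na(bias@times) | bias@times <= tmax)
  if (!length(keep)) return(numeric(length(s)))
  cen <- bias@centers[keep]; hei <- bias@heights[keep]
  sig <- bias@sigma; cut <- 6 * sig
  direct <- function(si) {
    d <- si - cen
    sel <- abs(d) <= cut
    if (any(sel)) sum(hei[sel] * exp(-d[sel]^2 / (2 * sig^2))) else 0
  }
  if (length(s) <= 512L) return(vapply(s, direct, numeric(1)))
  # long series: accumulate the Gaussians once on a fine grid (spacing
  # sigma/8, interpolation error < 1e-3 of the height) and interpolate
  lo <- min(min(s), min(cen) - cut); hi <- max(max(s), max(cen) + cut)
  nodes <- seq(lo, hi, by = sig / 8)
  if (nodes[length(nodes)] < hi) nodes <- c(nodes, hi)
  vg <- numeric(length(nodes))
  step <- nodes[2] - nodes[1]
  for (k in seq_along(cen)) {
    i0 <- max(1L, floor((cen[k] - cut - lo) / step) + 1L)
    i1 <- min(length(nodes), ceiling((cen[k] + cut - lo) / step) + 1L)
    idx <- i0:i1
    vg[idx] <- vg[idx] + hei[k] * exp(-(nodes[idx] - cen[k])^2 / (2 * sig^2))
  }
  stats::approx(nodes, vg, xout = s, rule = 2)$y
}

#' Deposit one well-tempered Gaussian
#'
#' Appends a Gaussian at centre \code{s} with height
#' \eqn{w \exp(-V(s)/(k_B \Delta T))}, \eqn{\Delta T = (\gamma - 1) T}.
#' The first deposition at a fresh centre therefore has height exactly
#' \code{params$height}.
#'
#' @param bias \code{BiasPotential}.
#' @param s CV value at which to deposit.
#' @param params \code{\link{metadParams}}.
#' @param time deposition time stamp (ps).
#' @return updated \code{BiasPotential}.
#' @export
depositGaussian <- function(bias, s, params, time = NA_real_) {
  stopifnot(inherits(params, "metadParams"))
  deltaT <- (params$gamma - 1) * params$temperature
  h <- if (is.infinite(params$gamma)) params$height else
    params$height * exp(-evaluateBias(bias, s) / (.kB * deltaT))
  initialize(bias,
             centers = c(bias@centers, s),
             heights = c(bias@heights, h),
             times = c(bias@times, time))
}

#' Geometric replica temperature ladder
#'
#' \eqn{T_k = T_{min} (T_{max}/T_{min})^{k/(n-1)}}: endpoints exact, constant
#' ratio between neighbours (targets uniform exchange acceptance).
#'
#' @param tMin,tMax temperature range, K (tMin < tMax).
#' @param nReplicas number of replicas (>= 2).
#' @return \code{\linkS4class{ReplicaLadder}}.
#' @export
buildLadder <- function(tMin, tMax, nReplicas) {
  if (nReplicas < 2) stop("a replica ladder needs at least 2 replicas")
  if (tMin >= tMax) stop("tMin must be below tMax")
  k <- seq(0, nReplicas - 1)
  temps <- tMin * (tMax / tMin)^(k / (nReplicas - 1))
  temps[1] <- tMin; temps[nReplicas] <- tMax
  new("ReplicaLadder", temperatures = temps,
      attempts = numeric(nReplicas - 1), accepts = numeric(nReplicas - 1))
}

## CV-domain and bias-grid geometry per potential form
cvDomain <- function(potential) {
  p <- potential@params
  switch(potential@form,
    "harmonic" = unname(p["x0"]) + c(-3, 3),
    "double-well-1d" = unname(p["L"]) * c(-4, 4),
    "flat-1d" = unname(p[c("lo", "hi")]) + c(-0.5, 0.5),
    "double-funnel-2d" = c(-1, 1) *
      unname(4 * max(abs(p[c("x1", "x2")])) + 8 * max(p[c("w1", "w2")])))
}

## shared driver around the compiled propagator
.runSegment <- function(potential, params, nSteps, seed, x0, cvIndex, step0,
                        biasV, biasF, gridBins, recordStride, metad,
                        temperature, pace = if (metad) params$pace else 0L) {
  dom <- cvDomain(potential)
  .runLangevinCpp(
    form = .formId[[potential@form]], params = unname(potential@params),
    x0 = x0, temperature = temperature,
    friction = attr(params, "friction") %||% 1, dt = attr(params, "dt") %||% 0.002,
    nsteps = as.integer(nSteps), seed = as.integer(seed), metad = metad,
    w = if (metad) params$height else 0,
    sigma = if (metad) params$sigma else 0.02,
    gammaFactor = if (metad) params$gamma else 8,
    pace = as.integer(pace),
    step0 = as.integer(step0), cvIndex = as.integer(cvIndex - 1L),
    gridLo = dom[1], gridHi = dom[2], gridBins = as.integer(gridBins),
    biasV = biasV, biasF = biasF,
    recordStride = as.integer(recordStride),
    domainLimit = 10 * max(abs(dom)))
}

.trajFromMatrix <- function(m, dim, temperature) {
  colnames(m) <- c("time", if (dim == 1L) "x" else c("x", "y"), "energy", "bias")
  cv <- m[, "x"]
  m <- cbind(m, cv = cv)
  new("CVTrajectory", data = m, temperature = temperature)
}

#' Unbiased (or externally biased) Langevin sampling on a toy potential
#'
#' Overdamped Langevin (Euler-Maruyama) propagation:
#' \eqn{x \leftarrow x - (\Delta t/\gamma_f) \nabla U +
#' \sqrt{2 k_B T \Delta t/\gamma_f}\, \xi}. With a bias supplied, the force
#' includes \eqn{-\nabla V_{bias}} along the CV coordinate. Bit-reproducible
#' per seed; diverging trajectories (|x| beyond 10x the domain) raise an
#' error advising a smaller time step.
#'
#' @param potential \code{ToyPotential}.
#' @param temperature kelvin (0 gives noiseless gradient descent).
#' @param friction friction coefficient, 1/ps.
#' @param dt time step, ps.
#' @param nSteps number of steps (>= 1).
#' @param seed integer seed.
#' @param bias optional \code{BiasPotential} held fixed during the run.
#' @param x0 initial coordinates (defaults to the domain centre).
#' @param recordStride record every k-th step.
#' @param cvIndex which coordinate is the CV (1-based).
#' @return \code{\linkS4class{CVTrajectory}}.
#' @export
langevinSample <- function(potential, temperature = 300, friction = 1,
                           dt = 0.002, nSteps = 1000L, seed = 1L,
                           bias = NULL, x0 = NULL, recordStride = 1L,
                           cvIndex = 1L) {
  stopifnot(nSteps >= 1)
  dom <- cvDomain(potential)
  if (is.null(x0)) x0 <- rep(mean(dom), potential@dim)
  gridBins <- 1000L
  biasV <- numeric(0); biasF <- numeric(0)
  useBias <- !is.null(bias) && length(bias@centers) > 0
  if (useBias) {
    nodes <- seq(dom[1], dom[2], length.out = gridBins + 1L)
    biasV <- evaluateBias(bias, nodes)
    # -dV/ds at the nodes from the Gaussian log
    sig <- bias@sigma
    biasF <- vapply(nodes, function(s) {
      d <- s - bias@centers
      sel <- abs(d) <= 6 * sig
      if (!any(sel)) return(0)
      sum(bias@heights[sel] * exp(-d[sel]^2 / (2 * sig^2)) * d[sel] / sig^2)
    }, numeric(1))
  }
  p <- metadParams(temperature = temperature)
  attr(p, "friction") <- friction; attr(p, "dt") <- dt
  # pace 0: the external bias is frozen, no depositions during the run
  res <- .runSegment(potential, p, nSteps, seed, x0, cvIndex, step0 = 0L,
                     biasV = biasV, biasF = biasF, gridBins = gridBins,
                     recordStride = recordStride, metad = useBias,
                     temperature = temperature, pace = 0L)
  .trajFromMatrix(res$traj, potential@dim, temperature)
}

#' Run well-tempered metadynamics on a toy potential
#'
#' Langevin propagation with the total force from the potential plus the
#' accumulated bias; one Gaussian deposited every \code{params$pace} steps.
#' The deposited-Gaussian log is timestamped for convergence analysis.
#'
#' @param potential \code{ToyPotential}.
#' @param params \code{\link{metadParams}}.
#' @param nSteps,seed run length and seed.
#' @param friction,dt integrator settings (1/ps, ps).
#' @param x0 initial coordinates.
#' @param cvIndex which coordinate is biased (1-based).
#' @param recordStride record every k-th step.
#' @param gridBins bias-grid resolution.
#' @return list with \code{trajectory} (\code{CVTrajectory}) and \code{bias}
#'   (\code{BiasPotential}).
#' @export
runMetadynamics <- function(potential, params = metadParams(), nSteps = 1e5,
                            seed = 1L, friction = 1, dt = 0.002, x0 = NULL,
                            cvIndex = 1L, recordStride = 10L,
                            gridBins = 2000L) {
  dom <- cvDomain(potential)
  if (is.null(x0)) x0 <- rep(mean(dom), potential@dim)
  attr(params, "friction") <- friction; attr(params, "dt") <- dt
  res <- .runSegment(potential, params, nSteps, seed, x0, cvIndex,
                     step0 = 0L, biasV = numeric(0), biasF = numeric(0),
                     gridBins = gridBins, recordStride = recordStride,
                     metad = TRUE, temperature = params$temperature)
  bias <- new("BiasPotential", centers = res$centers, heights = res$heights,
              times = res$times, sigma = params$sigma, gamma = params$gamma,
              temperature = params$temperature)
  list(trajectory = .trajFromMatrix(res$traj, potential@dim,
                                    params$temperature),
       bias = bias)
}

#' Well-tempered FES estimate from a converged bias
#'
#' \eqn{F(s) = -\gamma/(\gamma - 1)\, V(s) + C} with C fixed so the grid
#' minimum is zero; returned in RT units at the bias temperature.
#'
#' @param bias \code{BiasPotential}.
#' @param gridLo,gridHi,nbins grid geometry over the CV.
#' @param temperature analysis temperature, K (defaults to the bias T).
#' @param cvName axis name.
#' @param tmax include only Gaussians deposited at or before this time (ps).
#' @return \code{\linkS4class{FESGrid}} (1D, RT units).
#' @export
fesFromBias <- function(bias, gridLo, gridHi, nbins = 200L,
                        temperature = bias@temperature, cvName = "s",
                        tmax = Inf) {
  if (bias@gamma <= 1) stop("bias factor gamma must exceed 1")
  edges <- seq(gridLo, gridHi, length.out = nbins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  if (!length(bias@centers) || !any(bias@times <= tmax)) {
    warning("empty bias: returning a flat zero surface")
    v <- numeric(nbins)
  } else {
    v <- -bias@gamma / (bias@gamma - 1) * evaluateBias(bias, centers, tmax = tmax)
    v <- v / kBT(temperature)
  }
  makeFESGrid(axes = list(list(name = cvName, edges = edges)), values = v,
              mask = rep(FALSE, nbins), unit = "RT",
              temperature = temperature)
}

#' Replica-exchange acceptance decision
#'
#' Metropolis rule for parallel-tempering metadynamics: accept with
#' probability \eqn{\min(1, e^\Delta)} where
#' \eqn{\Delta = (\beta_i - \beta_j)(U_i - U_j) + \beta_i[V_i(s_i) - V_i(s_j)]
#' + \beta_j[V_j(s_j) - V_j(s_i)]}. On acceptance configurations swap while
#' each bias stays with its temperature slot.
#'
#' @param energyI,energyJ potential energies U(x_i), U(x_j), kJ/mol.
#' @param cvI,cvJ CV values s_i, s_j.
#' @param biasI,biasJ the two replicas' \code{BiasPotential}s (NULL = none).
#' @param tempI,tempJ replica temperatures, K.
#' @param u uniform random number for the decision.
#' @return list with \code{accept} (logical), \code{prob} and \code{delta}.
#' @export
attemptExchange <- function(energyI, energyJ, cvI, cvJ, biasI = NULL,
                            biasJ = NULL, tempI, tempJ, u = runif(1)) {
  bi <- 1 / kBT(tempI); bj <- 1 / kBT(tempJ)
  vI <- function(s) if (is.null(biasI)) 0 else evaluateBias(biasI, s)
  vJ <- function(s) if (is.null(biasJ)) 0 else evaluateBias(biasJ, s)
  delta <- (bi - bj) * (energyI - energyJ) +
    bi * (vI(cvI) - vI(cvJ)) + bj * (vJ(cvJ) - vJ(cvI))
  prob <- min(1, exp(delta))
  list(accept = u < prob, prob = prob, delta = delta)
}

#' Parallel-tempering metadynamics on a toy potential
#'
#' Interleaves per-replica well-tempered metadynamics with exchange attempts
#' between adjacent temperature pairs every \code{exchangeStride} steps
#' (alternating even/odd pairing). Biases are attached to temperature slots;
#' configurations swap. Deterministic per seed. Records per-pair acceptance
#' statistics and the replica-index occupancy over time (temperature-space
#' diffusion).
#'
#' @param potential \code{ToyPotential}.
#' @param ladder \code{ReplicaLadder}, or a numeric temperature vector (a
#'   single temperature degenerates to plain \code{\link{runMetadynamics}}).
#' @param params \code{\link{metadParams}} (its temperature field is taken
#'   per replica from the ladder).
#' @param nSteps total steps per replica.
#' @param exchangeStride steps between exchange attempts; must be a multiple
#'   of both \code{params$pace} and \code{recordStride} (deposition happens
#'   on the global step counter, so segment boundaries never skip or double
#'   a deposition).
#' @param seed global integer seed.
#' @param friction,dt,cvIndex,recordStride,gridBins as in
#'   \code{\link{runMetadynamics}}.
#' @return list with per-replica-slot \code{trajectories} and \code{biases},
#'   the updated \code{ladder} (exchange counters), \code{acceptanceRate}
#'   per adjacent pair, and \code{slotOfReplica} (segments+1 x nReplicas
#'   matrix tracing each starting replica through temperature space).
#' @export
runPTMetaD <- function(potential, ladder, params = metadParams(),
                       nSteps = 1e5, exchangeStride = 500L, seed = 1L,
                       friction = 1, dt = 0.002, cvIndex = 1L,
                       recordStride = 10L, gridBins = 2000L) {
  temps <- if (is(ladder, "ReplicaLadder")) ladder@temperatures else as.numeric(ladder)
  nrep <- length(temps)
  if (nrep == 1L) {
    one <- runMetadynamics(potential, metadParams(params$height, params$sigma,
                                                  params$gamma, params$pace,
                                                  temps[1]),
                           nSteps = nSteps, seed = seed, friction = friction,
                           dt = dt, cvIndex = cvIndex,
                           recordStride = recordStride, gridBins = gridBins)
    return(list(trajectories = list(one$trajectory),
                biases = list(one$bias), ladder = NULL,
                acceptanceRate = numeric(0),
                slotOfReplica = matrix(1L, 1, 1)))
  }
  if (exchangeStride %% params$pace != 0)
    stop("exchangeStride must be a multiple of the deposition pace")
  if (exchangeStride %% recordStride != 0)
    stop("exchangeStride must be a multiple of recordStride")
  nSeg <- floor(nSteps / exchangeStride)
  dom <- cvDomain(potential)
  nodes <- gridBins + 1L
  x <- lapply(seq_len(nrep), function(r) rep(mean(dom), potential@dim))
  biasV <- replicate(nrep, numeric(nodes), simplify = FALSE)
  biasF <- replicate(nrep, numeric(nodes), simplify = FALSE)
  gauss <- replicate(nrep, list(centers = numeric(), heights = numeric(),
                                times = numeric()), simplify = FALSE)
  trajRows <- replicate(nrep, list(), simplify = FALSE)
  attempts <- numeric(nrep - 1); accepts <- numeric(nrep - 1)
  replicaAtSlot <- seq_len(nrep)  # which starting replica sits in each slot
  slotOfReplica <- matrix(NA_integer_, nSeg + 1L, nrep)
  slotOfReplica[1, ] <- seq_len(nrep)
  lastU <- numeric(nrep)

  for (k in seq_len(nSeg)) {
    for (r in seq_len(nrep)) {
      p <- metadParams(params$height, params$sigma, params$gamma,
                       params$pace, temps[r])
      attr(p, "friction") <- friction; attr(p, "dt") <- dt
      res <- .runSegment(potential, p, exchangeStride,
                         seed = deriveSeed(seed, r, k),
                         x0 = x[[r]], cvIndex = cvIndex,
                         step0 = (k - 1L) * exchangeStride,
                         biasV = biasV[[r]], biasF = biasF[[r]],
                         gridBins = gridBins, recordStride = recordStride,
                         metad = TRUE, temperature = temps[r])
      x[[r]] <- res$xFinal
      biasV[[r]] <- res$biasV; biasF[[r]] <- res$biasF
      gauss[[r]]$centers <- c(gauss[[r]]$centers, res$centers)
      gauss[[r]]$heights <- c(gauss[[r]]$heights, res$heights)
      gauss[[r]]$times <- c(gauss[[r]]$times, res$times)
      m <- res$traj
      if (k > 1L) m <- m[-1, , drop = FALSE]
      trajRows[[r]][[k]] <- m
      lastU[r] <- m[nrow(m), potential@dim + 2L]
    }
    # adjacent-pair exchanges, alternating parity
    first <- if (k %% 2L == 1L) 1L else 2L
    pairs <- if (first > nrep - 1L) integer(0) else seq(first, nrep - 1L, by = 2L)
    us <- withSeed(deriveSeed(seed, 1000003L, k), runif(length(pairs)))
    nodesS <- seq(dom[1], dom[2], length.out = nodes)
    vAt <- function(r, s) stats::approx(nodesS, biasV[[r]], xout = s,
                                        rule = 2)$y
    for (pi in seq_along(pairs)) {
      i <- pairs[pi]; j <- i + 1L
      si <- x[[i]][cvIndex]; sj <- x[[j]][cvIndex]
      bi <- 1 / kBT(temps[i]); bj <- 1 / kBT(temps[j])
      delta <- (bi - bj) * (lastU[i] - lastU[j]) +
        bi * (vAt(i, si) - vAt(i, sj)) + bj * (vAt(j, sj) - vAt(j, si))
      dec <- list(accept = us[pi] < min(1, exp(delta)))
      attempts[i] <- attempts[i] + 1
      if (dec$accept) {
        accepts[i] <- accepts[i] + 1
        tmp <- x[[i]]; x[[i]] <- x[[j]]; x[[j]] <- tmp
        tmpU <- lastU[i]; lastU[i] <- lastU[j]; lastU[j] <- tmpU
        tmpR <- replicaAtSlot[i]
        replicaAtSlot[i] <- replicaAtSlot[j]; replicaAtSlot[j] <- tmpR
      }
    }
    slotOfReplica[k + 1L, ] <- match(seq_len(nrep), replicaAtSlot)
  }

  trajectories <- lapply(seq_len(nrep), function(r) {
    .trajFromMatrix(do.call(rbind, trajRows[[r]]), potential@dim, temps[r])
  })
  biases <- lapply(seq_len(nrep), function(r) {
    new("BiasPotential", centers = gauss[[r]]$centers,
        heights = gauss[[r]]$heights, times = gauss[[r]]$times,
        sigma = params$sigma, gamma = params$gamma, temperature = temps[r])
  })
  lad <- new("ReplicaLadder", temperatures = temps, attempts = attempts,
             accepts = accepts)
  list(trajectories = trajectories, biases = biases, ladder = lad,
       acceptanceRate = ifelse(attempts > 0, accepts / attempts, NA_real_),
       slotOfReplica = slotOfReplica)
}
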