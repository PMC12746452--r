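#' Default pipeline configuration
#'
#' The shipped end-to-end toy study: a folded three-helix bundle and its
#' melted counterpart for descriptor/HLDA fitting, a planted double-funnel
#' 2D potential for PT-metadynamics, FES construction, minimax pathway
#' extraction, and per-basin structural reports.
#'
#' @param seed global integer seed.
#' @param outdir output directory.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = tempfile("foldscape_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    nResidues = 76L,
    helices = list(I = c(1L, 27L), II = c(32L, 47L), III = c(50L, 69L)),
    apr = c(42L, 48L),
    generate = list(nFrames = 25L, jitterSigma = 0.015,
                    meltFraction = 27 / 76),
    descriptors = list(rmsdR0 = 0.08),
    metad = list(height = 3.0, sigma = 0.02, gamma = 8, pace = 100L,
                 nSteps = 3000000L, exchangeStride = 2000L,
                 recordStride = 50L, friction = 200, dt = 0.002),
    ladder = list(tMin = 300, tMax = 450, nReplicas = 4L),
    potential = list(form = "double-funnel-2d",
                     x1 = -0.12, y1 = 0, d1 = 18, w1 = 0.045,
                     x2 = 0.12, y2 = 0.03, d2 = 15, w2 = 0.045, kc = 1000),
    fes = list(nbins = 28L, minDepth = 0.75, maxEnergy = 5,
               burnFraction = 0.5),
    path = list(from = 1L, to = 2L),
    analysis = list(temperatures = c(300, 340, 380, 420, 450),
                    framesPerTemperature = 6L, sasaPoints = 240L))
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks (bias factor > 1, ladder ordering, APR
#' inside the chain, helix ranges valid and non-overlapping, melt fraction
#' in range). All violations are collected, not just the first.
#'
#' @param config configuration list (or a YAML file path).
#' @return character vector of violations (length 0 when valid).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- character()
  need <- c("seed", "outdir", "helices", "apr", "generate", "metad",
            "ladder", "potential", "fes", "path", "analysis")
  miss <- setdiff(need, names(config))
  if (length(miss)) v <- c(v, sprintf("missing section(s): %s",
                                      paste(miss, collapse = ", ")))
  if ("metad" %in% names(config)) {
    m <- config$metad
    if (!is.null(m$gamma) && m$gamma <= 1)
      v <- c(v, "metad$gamma: bias factor must exceed 1")
    if (!is.null(m$height) && m$height <= 0)
      v <- c(v, "metad$height: Gaussian height must be positive")
    if (!is.null(m$sigma) && m$sigma <= 0)
      v <- c(v, "metad$sigma: Gaussian width must be positive")
    if (!is.null(m$exchangeStride) && !is.null(m$pace) &&
        m$exchangeStride %% m$pace != 0)
      v <- c(v, "metad$exchangeStride must be a multiple of metad$pace")
  }
  if ("ladder" %in% names(config)) {
    l <- config$ladder
    if (!is.null(l$tMin) && !is.null(l$tMax) && l$tMin >= l$tMax)
      v <- c(v, "ladder: tMin must be below tMax")
    if (!is.null(l$nReplicas) && l$nReplicas < 1)
      v <- c(v, "ladder: nReplicas must be >= 1")
  }
  if (all(c("apr", "nResidues") %in% names(config))) {
    if (config$apr[1] < 1 || config$apr[2] > config$nResidues)
      v <- c(v, sprintf("apr [%d, %d] falls outside the %d-residue chain",
                        config$apr[1], config$apr[2], config$nResidues))
  }
  if ("helices" %in% names(config)) {
    ok <- tryCatch({
      do.call(helixDefinitions, config$helices); TRUE
    }, error = function(e) e$message)
    if (!isTRUE(ok)) v <- c(v, sprintf("helices: %s", ok))
  }
  if ("generate" %in% names(config)) {
    f <- config$generate$meltFraction
    if (!is.null(f) && (f < 0 || f > 1))
      v <- c(v, "generate$meltFraction must be in [0, 1]")
  }
  v
}

.pipelinePotential <- function(config) {
  p <- config$potential
  do.call(toyPotential, c(list(form = p$form), p[setdiff(names(p), "form")]))
}

.stageGenerate <- function(config) {
  g <- config$generate
  folded0 <- buildHelixBundle()
  melted0 <- meltHelix(folded0, g$meltFraction)
  folded <- jitterEnsemble(folded0, g$nFrames, g$jitterSigma,
                           seed = deriveSeed(config$seed, 1L, 1L))
  melted <- jitterEnsemble(melted0, g$nFrames, g$jitterSigma,
                           seed = deriveSeed(config$seed, 1L, 2L))
  writePDB(folded0, file.path(config$outdir, "reference.pdb"))
  writePDB(folded, file.path(config$outdir, "folded.pdb"))
  writePDB(melted, file.path(config$outdir, "unfolded.pdb"))
  c("reference.pdb", "folded.pdb", "unfolded.pdb")
}

.stageDescriptors <- function(config) {
  helices <- do.call(helixDefinitions, config$helices)
  ref <- readPDB(file.path(config$outdir, "reference.pdb"))
  folded <- readPDB(file.path(config$outdir, "folded.pdb"))
  melted <- readPDB(file.path(config$outdir, "unfolded.pdb"))
  sf <- computeDescriptorSeries(folded, helices, reference = ref,
                                rmsdR0 = config$descriptors$rmsdR0,
                                label = "folded")
  su <- computeDescriptorSeries(melted, helices, reference = ref,
                                rmsdR0 = config$descriptors$rmsdR0,
                                label = "unfolded")
  both <- DescriptorSeries(rbind(sf@values, su@values),
                           label = c(sf@label, su@label),
                           rg = c(sf@rg, su@rg))
  writeDescriptorSeries(both, file.path(config$outdir, "descriptors.colvar"))
  c("descriptors.colvar", "descriptors.colvar.labels")
}

.stageHlda <- function(config) {
  series <- readDescriptorSeries(file.path(config$outdir, "descriptors.colvar"))
  model <- hldaFit(series, labels = c("folded", "unfolded"))
  exportCVDefinition(model, file.path(config$outdir, "cv_definition.txt"))
  yaml::write_yaml(list(weights = as.numeric(model@weights),
                        eigenvalues = as.numeric(model@eigenvalues),
                        separation = model@separation,
                        descriptors = model@descriptorNames),
                   file.path(config$outdir, "hlda_model.yaml"))
  c("cv_definition.txt", "hlda_model.yaml")
}

.stageMetad <- function(config) {
  pot <- .pipelinePotential(config)
  m <- config$metad
  l <- config$ladder
  temps <- if (l$nReplicas == 1L) l$tMin else NULL
  ladder <- if (l$nReplicas > 1L) buildLadder(l$tMin, l$tMax, l$nReplicas) else l$tMin
  params <- metadParams(m$height, m$sigma, m$gamma, m$pace, l$tMin)
  run <- runPTMetaD(pot, ladder, params, nSteps = m$nSteps,
                    exchangeStride = m$exchangeStride,
                    seed = deriveSeed(config$seed, 4L, 1L),
                    friction = m$friction, dt = m$dt,
                    recordStride = m$recordStride)
  files <- character()
  for (r in seq_along(run$trajectories)) {
    cf <- sprintf("colvar_r%d.dat", r)
    hf <- sprintf("hills_r%d.dat", r)
    writeColvar(trajectoryData(run$trajectories[[r]]),
                file.path(config$outdir, cf))
    writeHills(run$biases[[r]], file.path(config$outdir, hf))
    files <- c(files, cf, hf)
  }
  yaml::write_yaml(list(temperatures = as.numeric(if (is(ladder, "ReplicaLadder"))
                          ladder@temperatures else ladder),
                        acceptanceRate = as.numeric(run$acceptanceRate),
                        roundTrips = .countRoundTrips(run$slotOfReplica)),
                   file.path(config$outdir, "ladder_stats.yaml"))
  c(files, "ladder_stats.yaml")
}

## round trips (bottom slot -> top slot -> bottom) completed per replica
.countRoundTrips <- function(slotOfReplica) {
  nrep <- ncol(slotOfReplica)
  vapply(seq_len(nrep), function(r) {
    s <- slotOfReplica[, r]
    trips <- 0L; phase <- 0L
    for (v in s) {
      if (phase == 0L && v == nrep) phase <- 1L
      if (phase == 1L && v == 1L) { trips <- trips + 1L; phase <- 0L }
    }
    trips
  }, integer(1))
}

.stageFes <- function(config) {
  m <- config$metad
  traj <- readColvar(file.path(config$outdir, "colvar_r1.dat"))
  bias <- readHills(file.path(config$outdir, "hills_r1.dat"),
                    temperature = config$ladder$tMin)
  # discard the burn-in during which the bias is still filling: the
  # final-bias estimators are only meaningful once the bias is quasi-static
  burn <- config$fes$burnFraction %||% 0.5
  keep <- seq(floor(burn * nrow(traj)) + 1L, nrow(traj))
  traj <- traj[keep, , drop = FALSE]
  # 2D surface via the factorized estimator F(x, y) = F_x(x) - kT ln p(y|x):
  # only x is biased, so the conditional of y given x in the biased run is
  # already unbiased, and the x-marginal comes from the converged bias
  # (bin-averaged to integrate out the sigma-scale Gaussian granularity).
  # This avoids the exp(V/kT) weight spread of histogram reweighting, whose
  # variance at this run length would drown the shallower basin.
  nbins <- config$fes$nbins
  kT <- kBT(config$ladder$tMin)
  ex <- seq(min(traj$x), max(traj$x), length.out = nbins + 1L)
  ey <- seq(min(traj$y), max(traj$y), length.out = nbins + 1L)
  ix <- .binIndex(traj$x, ex)
  iy <- .binIndex(traj$y, ey)
  cnt <- matrix(0, nbins, nbins)
  tab <- table(factor(ix, levels = seq_len(nbins)),
               factor(iy, levels = seq_len(nbins)))
  cnt[] <- as.numeric(tab)
  fine <- seq(ex[1], ex[nbins + 1L], length.out = nbins * 10L + 1L)
  fxFine <- -bias@gamma / (bias@gamma - 1) * evaluateBias(bias, fine) / kT
  fx <- vapply(seq_len(nbins), function(i)
    mean(fxFine[fine >= ex[i] & fine <= ex[i + 1L]]), numeric(1))
  condF <- -log(sweep(cnt, 1, pmax(rowSums(cnt), 1), "/"))
  vals <- sweep(condF, 1, fx, "+")
  mask <- cnt == 0
  fes2 <- makeFESGrid(axes = list(list(name = "x", edges = ex),
                                  list(name = "y", edges = ey)),
                      values = vals, mask = mask, unit = "RT",
                      temperature = config$ladder$tMin)
  writeFESGrid(fes2, file.path(config$outdir, "fes2d.dat"))
  dom <- cvDomain(.pipelinePotential(config))
  fes1 <- fesFromBias(bias, dom[1], dom[2], nbins = 200L)
  writeFESGrid(fes1, file.path(config$outdir, "fes1d.dat"))
  tEnd <- max(bias@times)
  snaps <- fesTimeSeries(bias, dom[1], dom[2], nbins = 100L,
                         times = tEnd * c(0.25, 0.5, 0.75, 1))
  yaml::write_yaml(list(snapshotTimes = as.numeric(tEnd * c(0.25, 0.5, 0.75, 1)),
                        deviationsRT = as.numeric(snaps$deviations)),
                   file.path(config$outdir, "convergence.yaml"))
  c("fes2d.dat", "fes1d.dat", "convergence.yaml")
}

.stagePath <- function(config) {
  fes <- readFESGrid(file.path(config$outdir, "fes2d.dat"))
  basins <- findMinima(fes, minDepth = config$fes$minDepth,
                       maxEnergy = config$fes$maxEnergy %||% Inf)
  write.table(basins, file.path(config$outdir, "basins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  from <- config$path$from; to <- config$path$to
  if (all(c(from, to) %in% basins$label)) {
    path <- minimumEnergyPath(fes, basins, from, to)
    pdf_ <- data.frame(path$nodes, energy = path$energies)
    names(pdf_) <- c(paste0("i", seq_len(ncol(path$nodes))), "energy")
    write.table(pdf_, file.path(config$outdir, "path.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bar <- barriersAlongPath(path, basins)
    write.table(bar$legs, file.path(config$outdir, "barriers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop(sprintf("requested path endpoints %d -> %d not among basin labels (%s)",
                 from, to, paste(basins$label, collapse = ", ")))
  }
  c("basins.tsv", "path.tsv", "barriers.tsv")
}

.stageAnalyze <- function(config) {
  helices <- do.call(helixDefinitions, config$helices)
  ref <- readPDB(file.path(config$outdir, "reference.pdb"))
  folded <- readPDB(file.path(config$outdir, "folded.pdb"))
  melted <- readPDB(file.path(config$outdir, "unfolded.pdb"))
  apr <- config$apr
  np <- config$analysis$sasaPoints
  reports <- list(
    basin1 = basinReport(folded, 1L, helices, ref, apr, sasaPoints = np),
    basin2 = basinReport(melted, 2L, helices, ref, apr, sasaPoints = np))
  yaml::write_yaml(lapply(reports, function(r) list(
    label = r$label, frames = r$frames,
    helicity = as.numeric(r$helicity),
    helixPct = 100 * as.numeric(r$ssPopulation["helix"]),
    coilPct = 100 * as.numeric(r$ssPopulation["coil"]),
    rg = r$rg,
    sasaTotal = r$sasaTotal, sasaHydrophobic = r$sasaHydrophobic,
    sasaApr = r$sasaApr)),
    file.path(config$outdir, "basin_reports.yaml"))
  # temperature ladder fixture: progressively melted ensembles
  temps <- config$analysis$temperatures
  nT <- length(temps)
  base <- buildHelixBundle()
  sets <- lapply(seq_len(nT), function(k) {
    frac <- (k - 1) / (nT - 1)
    st <- meltHelix(base, frac)
    jitterEnsemble(st, config$analysis$framesPerTemperature, 0.01,
                   seed = deriveSeed(config$seed, 7L, k))
  })
  prof <- temperatureSSProfile(sets, temperatures = temps)
  write.table(prof, file.path(config$outdir, "temperature_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  c("basin_reports.yaml", "temperature_profile.tsv")
}

#' Run the end-to-end pipeline
#'
#' Executes the seven stages (generate, descriptors, hlda, metad, fes, path,
#' analyze) in order, writing each stage's artifacts under
#' \code{config$outdir} plus a manifest (parameters, per-stage seeds, output
#' checksums, timings). Stages communicate exclusively through files, so a
#' resumed run (\code{resume = TRUE} skips stages whose outputs exist)
#' produces bit-identical downstream artifacts.
#'
#' @param config configuration list from
#'   \code{\link{defaultPipelineConfig}} (or a YAML path).
#' @param resume skip stages whose outputs already exist.
#' @return manifest list, invisibly; also written as \code{manifest.yaml}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  violations <- validateConfig(config)
  if (length(violations))
    stop(paste(c("invalid configuration:", violations), collapse = "\n  "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(generate = .stageGenerate, descriptors = .stageDescriptors,
                 hlda = .stageHlda, metad = .stageMetad, fes = .stageFes,
                 path = .stagePath, analyze = .stageAnalyze)
  manifest <- list(seed = config$seed, outdir = config$outdir,
                   stages = list())
  for (nm in names(stages)) {
    t0 <- Sys.time()
    prior <- file.path(config$outdir, paste0(".done_", nm))
    if (resume && file.exists(prior)) {
      outputs <- readLines(prior)
      status <- "resumed"
    } else {
      outputs <- tryCatch(stages[[nm]](config), error = function(e)
        stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
             call. = FALSE))
      writeLines(outputs, prior)
      status <- "complete"
    }
    paths <- file.path(config$outdir, outputs)
    manifest$stages[[nm]] <- list(
      status = status, outputs = outputs,
      md5 = unname(tools::md5sum(paths)),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  manifest$config <- config
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(manifest)
}
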