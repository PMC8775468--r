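# Pipeline orchestration: validated configuration, stage sequencing and
# artifact writing.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    frameRate = NULL,          # required, frames/s
    umPerPixel = 20,
    simulation = list(
      nCells = 45L, fieldSize = c(1000, 1000), nFrames = 1200L,
      transientRate = 1.34, transientDuration = 12.37,
      transientAmplitude = 10, noiseSd = 1, inactiveFraction = 0.4,
      couplingScale = 1, nPlantedEdges = 40L, lagRange = c(2L, 8L),
      maxOutDegree = 2L, maxInDegree = 2L, couplingProb = 0.6),
    events = list(thresholdMultiplier = 1, minDurationS = 4,
                  deviationMode = "sd", bridgeFrames = 2L),
    network = list(w = NULL, W = 10L, rhoThreshold = 0.3,
                   mode = "directed", strictLag = FALSE),
    metrics = list(contactSlack = 1.2),
    movie = list(render = FALSE, imageShape = c(64L, 64L)),
    bursts = list(simulate = TRUE, nElectrodes = 15L, durationMin = 10,
                  nBursts = 36L, nElectrodesPerBurst = 6L,
                  spikesPerElectrode = 15L, backgroundRate = 0.1,
                  minElectrodes = 4L, maxGapMs = 100),
    inputs = list(traces = NULL, cellMap = NULL, spikes = NULL,
                  spikesDurationMin = NULL))
}

mergeSection <- function(given, defaults, section) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, given)
}

#' Validate a pipeline configuration
#'
#' Fills in defaults, rejects unknown keys, and checks the required
#' fields before any stage runs. A configuration may come from
#' \code{\link{readPipelineConfig}} or be built as a plain list.
#'
#' @param config named list; see \code{pipelineDefaults} in the package
#'   source for the recognised sections and keys.
#' @return the completed configuration list.
#' @export
validatePipelineConfig <- function(config) {
  defs <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  top <- utils::modifyList(
    defs[c("seed", "frameRate", "umPerPixel")],
    config[intersect(names(config),
                     c("seed", "frameRate", "umPerPixel"))])
  out <- top
  for (sec in c("simulation", "events", "network", "metrics", "movie",
                "bursts", "inputs"))
    out[[sec]] <- mergeSection(config[[sec]], defs[[sec]], sec)
  if (is.null(out$frameRate))
    stop("configuration is missing required field 'frameRate'",
         call. = FALSE)
  assertScalarNumeric(out$frameRate, "frameRate", positive = TRUE)
  assertScalarNumeric(out$seed, "seed")
  out
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages simulate (or load) -> detect events ->
#' (render and segment movie) -> infer network -> network metrics ->
#' MEA bursts, writing every stage's artifacts plus provenance into
#' \code{outDir}. Identical configurations produce byte-identical
#' analysis artifacts (the provenance file carries the only timestamp).
#'
#' @param config configuration list (validated internally).
#' @param outDir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{traces}, \code{groundTruth}, \code{events},
#'   \code{activity}, \code{pairs}, \code{network}, \code{metrics},
#'   \code{recovery}, \code{burstSet}, \code{burstSummary},
#'   \code{summary}).
#' @export
runPipeline <- function(config, outDir) {
  cfg <- validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fr <- cfg$frameRate
  truth <- NULL

  # -- stage 1: traces ------------------------------------------------
  if (!is.null(cfg$inputs$traces)) {
    tm <- readTraces(cfg$inputs$traces, frameRate = fr)
    cellMap <- if (!is.null(cfg$inputs$cellMap))
      readCellMap(cfg$inputs$cellMap) else NULL
  } else {
    sim <- cfg$simulation
    edges <- if (sim$nPlantedEdges > 0)
      plantRandomNetwork(sim$nCells, sim$nPlantedEdges,
                         maxOutDegree = sim$maxOutDegree,
                         maxInDegree = sim$maxInDegree,
                         lagRange = sim$lagRange,
                         prob = sim$couplingProb, seed = cfg$seed)
      else data.frame(from = integer(0), to = integer(0),
                      lag = integer(0), prob = numeric(0))
    sc <- SimulationConfig(
      nCells = sim$nCells, fieldSize = sim$fieldSize, frameRate = fr,
      nFrames = sim$nFrames, transientRate = sim$transientRate,
      transientDuration = sim$transientDuration,
      transientAmplitude = sim$transientAmplitude,
      noiseSd = sim$noiseSd, plantedEdges = edges,
      couplingScale = sim$couplingScale,
      inactiveFraction = sim$inactiveFraction, seed = cfg$seed)
    res <- simulateTraces(sc)
    tm <- res$traces
    truth <- res$groundTruth
    cellMap <- truth$cellMap
    writeCellMap(cellMap, file.path(outDir, "cell_map.csv"))
    writeTraces(tm, file.path(outDir, "traces.csv"))
    writeJsonArtifact(
      list(events = truth$events,
           planted_edges = networkEdges(truth$plantedNetwork),
           active_cells = truth$activeCells),
      file.path(outDir, "ground_truth.json"))
  }

  # -- stage 2: calcium events ----------------------------------------
  ev <- detectEvents(tm,
                     thresholdMultiplier = cfg$events$thresholdMultiplier,
                     minDurationS = cfg$events$minDurationS,
                     deviationMode = cfg$events$deviationMode,
                     bridgeFrames = cfg$events$bridgeFrames)
  durMin <- nFrames(tm) / fr / 60
  act <- summarizeActivity(ev, nCells = nrow(tm), durationMin = durMin)
  utils::write.csv(ev, file.path(outDir, "events.csv"),
                   row.names = FALSE)
  writeJsonArtifact(act[c("shareActivePct", "meanFrequencyPerMin",
                          "meanDurationS")],
                    file.path(outDir, "activity_summary.json"))

  # -- stage 3 (optional): movie rendering + segmentation -------------
  if (isTRUE(cfg$movie$render) && !is.null(cellMap)) {
    movie <- renderMovie(tm, cellMap, imageShape = cfg$movie$imageShape,
                         umPerPixel = cfg$umPerPixel)
    rng <- max(1, 2^ceiling(log2(max(abs(movie)) + 1e-9)))
    writeMovie(movie, file.path(outDir, "movie.tif"),
               dynamicRange = rng)
    evs <- findActivityEvents(movie)
    sig <- extractCellSignals(evs, movie, cellMap = cellMap,
                              umPerPixel = cfg$umPerPixel)
    utils::write.csv(sig, file.path(outDir, "cell_signals.csv"),
                     row.names = FALSE)
  }

  # -- stage 4: network inference -------------------------------------
  prs <- pairwiseCorrelations(tm, w = cfg$network$w, W = cfg$network$W)
  net <- buildNetwork(prs, cellMap = cellMap,
                      rhoThreshold = cfg$network$rhoThreshold,
                      mode = cfg$network$mode,
                      strictLag = cfg$network$strictLag,
                      frameRate = fr)
  utils::write.csv(networkEdges(net),
                   file.path(outDir, "network_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(prs, file.path(outDir, "pair_correlations.csv"),
                   row.names = FALSE)
  writeNetworkGraphML(net, file.path(outDir, "network.graphml"))

  # -- stage 5: network metrics ---------------------------------------
  met <- recov <- NULL
  if (!is.null(cellMap) && length(cellMap) >= 2L) {
    met <- networkMetrics(net, prs, cellMap,
                          contactSlack = cfg$metrics$contactSlack)
    writeJsonArtifact(metricsAsList(met),
                      file.path(outDir, "metrics.json"))
  }
  if (!is.null(truth))
    recov <- edgeRecoveryStats(net, truth$plantedNetwork)

  # -- stage 6: MEA bursts --------------------------------------------
  bset <- bsum <- NULL
  if (!is.null(cfg$inputs$spikes)) {
    rec <- readSpikes(cfg$inputs$spikes,
                      durationMin = cfg$inputs$spikesDurationMin)
    burstDur <- cfg$inputs$spikesDurationMin
  } else if (isTRUE(cfg$bursts$simulate)) {
    bs <- cfg$bursts
    spk <- simulateSpikes(
      nElectrodes = bs$nElectrodes, durationMin = bs$durationMin,
      nBursts = bs$nBursts,
      nElectrodesPerBurst = bs$nElectrodesPerBurst,
      spikesPerElectrode = bs$spikesPerElectrode,
      backgroundRate = bs$backgroundRate, maxGapMs = bs$maxGapMs,
      seed = cfg$seed)
    rec <- spk$recording
    burstDur <- bs$durationMin
    writeSpikes(rec, file.path(outDir, "spikes.csv"))
  } else rec <- NULL
  if (!is.null(rec)) {
    bset <- detectBursts(rec, minElectrodes = cfg$bursts$minElectrodes,
                         maxGapMs = cfg$bursts$maxGapMs)
    bsum <- summarizeBursts(bset, durationMin = burstDur)
    utils::write.csv(bursts(bset), file.path(outDir, "bursts.csv"),
                     row.names = FALSE)
    if (nrow(bursts(bset))) {
      pat <- do.call(rbind, lapply(bursts(bset)$burst_id, function(b)
        cbind(burst_id = b, activationPattern(bset, b))))
      utils::write.csv(pat,
                       file.path(outDir, "activation_patterns.csv"),
                       row.names = FALSE)
    }
    writeJsonArtifact(bsum, file.path(outDir, "burst_summary.json"))
  }

  # -- summary + provenance -------------------------------------------
  summary <- list(
    n_cells = nrow(tm),
    duration_min = durMin,
    activity = act[c("shareActivePct", "meanFrequencyPerMin",
                     "meanDurationS")],
    network = if (!is.null(met)) metricsAsList(met) else NULL,
    edge_recovery = recov,
    bursts = bsum)
  writeJsonArtifact(summary, file.path(outDir, "summary.json"))
  writeProvenance(
    stage = "pipeline",
    params = cfg[setdiff(names(cfg), "inputs")],
    inputs = unlist(Filter(Negate(is.null), cfg$inputs)),
    path = file.path(outDir, "provenance.json"))

  invisible(list(traces = tm, groundTruth = truth, events = ev,
                 activity = act, pairs = prs, network = net,
                 metrics = met, recovery = recov, burstSet = bset,
                 burstSummary = bsum, summary = summary))
}
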