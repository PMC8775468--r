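#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of a synthetic calcium-imaging recording
#'
#' Bundles every parameter of the synthetic-data generator: the cell field,
#' the recording geometry, the statistics of spontaneous calcium transients,
#' additive noise, and the planted directed coupling network. The defaults
#' emulate a 21-DIV primary hippocampal culture imaged for ten minutes:
#' a seeding density of 4500 cells/cm^2 (45 cells on a 1000 x 1000 um field),
#' transients of 12.37 s at 1.34 oscillations/min in roughly 59% of cells.
#'
#' @slot nCells number of cells placed on the field.
#' @slot fieldSize width and height of the field in micrometres.
#' @slot frameRate acquisition rate in frames per second.
#' @slot nFrames number of recorded frames.
#' @slot transientRate spontaneous event rate per active cell
#'   (events per minute).
#' @slot transientDuration nominal transient duration in seconds.
#' @slot transientAmplitude peak transient amplitude (arbitrary
#'   fluorescence units).
#' @slot noiseSd standard deviation of additive Gaussian noise (same units).
#' @slot plantedEdges data.frame with columns \code{from}, \code{to},
#'   \code{lag} (frames, signed) and \code{prob} (coupling probability);
#'   each event of \code{from} is copied into \code{to} shifted by
#'   \code{lag} frames with probability \code{prob}.
#' @slot couplingScale amplitude factor applied to copied transients; 1
#'   makes coupled events exact copies of the source.
#' @slot inactiveFraction fraction of cells that never fire spontaneously.
#' @slot inactiveCells explicit indices of the cells that never fire
#'   spontaneously; when non-empty it overrides \code{inactiveFraction}.
#'   Cells in this set still relay coupled events planted into them, so
#'   a feed-forward scenario can drive passive followers from
#'   autonomously active sources.
#' @slot seed root seed; all generator streams derive from it, so one
#'   config yields bit-identical output every time.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nCells = "integer", fieldSize = "numeric", frameRate = "numeric",
    nFrames = "integer", transientRate = "numeric",
    transientDuration = "numeric", transientAmplitude = "numeric",
    noiseSd = "numeric", plantedEdges = "data.frame",
    couplingScale = "numeric", inactiveFraction = "numeric",
    inactiveCells = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive lengths (um)")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@inactiveFraction < 0 || object@inactiveFraction > 1)
    msg <- c(msg, "inactiveFraction must be in [0, 1]")
  if (length(object@inactiveCells) &&
      (any(object@inactiveCells < 1L) ||
       any(object@inactiveCells > object@nCells)))
    msg <- c(msg, "inactiveCells must index cells in 1..nCells")
  if (object@couplingScale < 0) msg <- c(msg, "couplingScale must be >= 0")
  pe <- object@plantedEdges
  if (nrow(pe)) {
    need <- c("from", "to", "lag", "prob")
    if (!all(need %in% names(pe)))
      msg <- c(msg, "plantedEdges needs columns from, to, lag, prob")
    else {
      if (any(pe$from < 1 | pe$from > object@nCells |
              pe$to < 1 | pe$to > object@nCells))
        msg <- c(msg, "plantedEdges reference cells outside 1..nCells")
      if (any(abs(pe$lag) >= object@nFrames))
        msg <- c(msg, "planted lags must be smaller than nFrames")
      if (any(pe$prob < 0 | pe$prob > 1))
        msg <- c(msg, "coupling probabilities must be in [0, 1]")
      if (any(pe$from == pe$to))
        msg <- c(msg, "self-coupling (from == to) is not allowed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Create a SimulationConfig
#'
#' @param nCells,fieldSize,frameRate,nFrames,transientRate,transientDuration,transientAmplitude,noiseSd,plantedEdges,couplingScale,inactiveFraction,inactiveCells,seed
#'   see the class documentation \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(nCells = 10, nFrames = 200, seed = 1)
#' @export
SimulationConfig <- function(nCells = 45, fieldSize = c(1000, 1000),
                             frameRate = 2, nFrames = 1200,
                             transientRate = 1.34,
                             transientDuration = 12.37,
                             transientAmplitude = 10, noiseSd = 1,
                             plantedEdges = data.frame(
                               from = integer(0), to = integer(0),
                               lag = integer(0), prob = numeric(0)),
                             couplingScale = 1,
                             inactiveFraction = 0.4,
                             inactiveCells = integer(0), seed = 1L) {
  new("SimulationConfig",
      nCells = as.integer(nCells), fieldSize = as.numeric(fieldSize),
      frameRate = as.numeric(frameRate), nFrames = as.integer(nFrames),
      transientRate = as.numeric(transientRate),
      transientDuration = as.numeric(transientDuration),
      transientAmplitude = as.numeric(transientAmplitude),
      noiseSd = as.numeric(noiseSd),
      plantedEdges = as.data.frame(plantedEdges),
      couplingScale = as.numeric(couplingScale),
      inactiveFraction = as.numeric(inactiveFraction),
      inactiveCells = as.integer(inactiveCells),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# TraceMatrix
# ---------------------------------------------------------------------------

#' Per-cell fluorescence time series
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"fluorescence"}) holds one row per cell and one column per frame;
#' the acquisition rate (frames/s) lives in \code{metadata(x)$frameRate}.
#' Column data carry the frame times in seconds.
#'
#' @export
setClass("TraceMatrix", contains = "SummarizedExperiment")

setValidity("TraceMatrix", function(object) {
  fr <- S4Vectors::metadata(object)$frameRate
  if (is.null(fr) || !is.numeric(fr) || length(fr) != 1L ||
      !is.finite(fr) || fr <= 0)
    return("metadata(x)$frameRate must be a single positive number")
  if (!"fluorescence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'fluorescence' is missing")
  TRUE
})

#' Create a TraceMatrix
#'
#' @param values numeric matrix of fluorescence intensities, frames in rows
#'   and cells in columns (the on-disk CSV layout).
#' @param frameRate acquisition rate in frames per second.
#' @param cellIds optional cell identifiers; defaults to the column names
#'   of \code{values} or \code{cell_1 ... cell_n}.
#' @return a \linkS4class{TraceMatrix}.
#' @examples
#' tm <- TraceMatrix(matrix(rnorm(200), 100, 2), frameRate = 2)
#' frameRate(tm)
#' @export
TraceMatrix <- function(values, frameRate, cellIds = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L) storage.mode(values) <- "double"
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  assertScalarNumeric(frameRate, "frameRate", positive = TRUE)
  if (is.null(cellIds)) cellIds <- colnames(values)
  if (is.null(cellIds))
    cellIds <- sprintf("cell_%d", seq_len(ncol(values)))
  cellIds <- as.character(cellIds)
  if (length(cellIds) != ncol(values))
    stop("length(cellIds) must equal the number of cells")
  a <- t(values)
  rownames(a) <- as.character(cellIds)
  colnames(a) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(fluorescence = a),
    colData = S4Vectors::DataFrame(
      time_s = (seq_len(ncol(a)) - 1) / frameRate))
  S4Vectors::metadata(se)$frameRate <- as.numeric(frameRate)
  new("TraceMatrix", se)
}

# ---------------------------------------------------------------------------
# CellMap
# ---------------------------------------------------------------------------

#' Map of cell somata on the imaging field
#'
#' Holds one disc per cell: identifier, centroid coordinates and radius,
#' all in micrometres. Used for rendering synthetic movies, for spatial
#' adjacency (somata in direct contact) and for signal-propagation speed.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{radius_um}.
#' @export
setClass("CellMap", representation(cells = "data.frame"))

setValidity("CellMap", function(object) {
  d <- object@cells
  need <- c("cell_id", "x_um", "y_um", "radius_um")
  if (!all(need %in% names(d)))
    return("cells needs columns cell_id, x_um, y_um, radius_um")
  if (anyDuplicated(d$cell_id)) return("cell_id values must be unique")
  if (nrow(d) && any(d$radius_um <= 0)) return("radii must be > 0")
  TRUE
})

#' Create a CellMap
#' @param cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{radius_um}.
#' @return a \linkS4class{CellMap}.
#' @export
CellMap <- function(cells) {
  cells <- as.data.frame(cells)
  new("CellMap", cells = cells)
}

# ---------------------------------------------------------------------------
# FunctionalNetwork
# ---------------------------------------------------------------------------

#' Functional network of correlated cells
#'
#' A graph whose vertices are cells and whose edges join pairs whose
#' (lag-maximised) activity correlation exceeds a threshold. In directed
#' mode the sign of the optimal lag orients the edge from the leading to
#' the lagging cell; pairs whose optimum sits at zero lag can be kept as
#' undirected edges (\code{directed == FALSE} in the edge table).
#'
#' @slot nodes data.frame with \code{cell_id} and, when known, \code{x_um},
#'   \code{y_um}.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{weight} (the correlation that admitted the edge), \code{lag}
#'   (frames, signed; NA when unknown) and \code{directed} (logical).
#' @slot rhoThreshold the correlation threshold used to admit edges.
#' @slot mode \code{"undirected"} or \code{"directed"}.
#' @slot frameRate frames/s of the source recording (NA when unknown);
#'   needed to express propagation speed in um/s.
#' @export
setClass("FunctionalNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 rhoThreshold = "numeric", mode = "character",
                 frameRate = "numeric"))

setValidity("FunctionalNetwork", function(object) {
  e <- object@edges
  need <- c("from", "to", "weight", "lag", "directed")
  if (!all(need %in% names(e)))
    return("edges needs columns from, to, weight, lag, directed")
  if (!"cell_id" %in% names(object@nodes))
    return("nodes needs a cell_id column")
  if (nrow(e)) {
    ids <- object@nodes$cell_id
    if (!all(e$from %in% ids) || !all(e$to %in% ids))
      return("edges reference unknown cells")
    if (any(e$from == e$to)) return("self-edges are not allowed")
    if (is.finite(object@rhoThreshold) &&
        any(e$weight <= object@rhoThreshold))
      return("every edge weight must exceed rhoThreshold")
  }
  if (!object@mode %in% c("undirected", "directed"))
    return("mode must be 'undirected' or 'directed'")
  TRUE
})

#' Create a FunctionalNetwork
#' @param nodes data.frame with \code{cell_id} (and optional coordinates).
#' @param edges data.frame with \code{from}, \code{to}, \code{weight},
#'   \code{lag}, \code{directed}.
#' @param rhoThreshold correlation threshold used to admit the edges.
#' @param mode \code{"undirected"} or \code{"directed"}.
#' @param frameRate frames/s of the source recording (NA if unknown).
#' @return a \linkS4class{FunctionalNetwork}.
#' @export
FunctionalNetwork <- function(nodes, edges, rhoThreshold = NA_real_,
                              mode = "undirected", frameRate = NA_real_) {
  if (!nrow(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), lag = numeric(0),
                        directed = logical(0))
  }
  new("FunctionalNetwork", nodes = as.data.frame(nodes),
      edges = as.data.frame(edges),
      rhoThreshold = as.numeric(rhoThreshold), mode = mode,
      frameRate = as.numeric(frameRate))
}

# ---------------------------------------------------------------------------
# SpikeRecording
# ---------------------------------------------------------------------------

#' Multi-electrode array spike recording
#'
#' Extracellular action-potential times pooled over the electrodes of an
#' array. Spikes are sorted by time (ties broken by electrode id so that
#' burst grouping is deterministic).
#'
#' @slot spikes data.frame with \code{electrode_id}, \code{time_ms}.
#' @slot durationMin recording duration in minutes.
#' @slot layout data.frame with \code{electrode_id}, \code{row},
#'   \code{col} describing the array geometry (may be empty).
#' @export
setClass("SpikeRecording",
  representation(spikes = "data.frame", durationMin = "numeric",
                 layout = "data.frame"))

setValidity("SpikeRecording", function(object) {
  s <- object@spikes
  if (!all(c("electrode_id", "time_ms") %in% names(s)))
    return("spikes needs columns electrode_id, time_ms")
  if (object@durationMin <= 0) return("durationMin must be > 0")
  if (nrow(s)) {
    if (any(s$time_ms < 0 | s$time_ms > object@durationMin * 60000))
      return("spike times must lie within the recording")
    if (is.unsorted(s$time_ms)) return("spikes must be sorted by time")
  }
  TRUE
})

#' Create a SpikeRecording
#' @param spikes data.frame with \code{electrode_id} and \code{time_ms}.
#' @param durationMin recording duration in minutes.
#' @param layout optional electrode layout (\code{electrode_id},
#'   \code{row}, \code{col}).
#' @return a \linkS4class{SpikeRecording} with spikes sorted by
#'   (time, electrode).
#' @export
SpikeRecording <- function(spikes, durationMin, layout = NULL) {
  spikes <- as.data.frame(spikes)
  if (nrow(spikes))
    spikes <- spikes[order(spikes$time_ms, spikes$electrode_id), ,
                     drop = FALSE]
  rownames(spikes) <- NULL
  if (is.null(layout))
    layout <- data.frame(electrode_id = integer(0), row = integer(0),
                         col = integer(0))
  new("SpikeRecording", spikes = spikes,
      durationMin = as.numeric(durationMin),
      layout = as.data.frame(layout))
}

# ---------------------------------------------------------------------------
# BurstSet
# ---------------------------------------------------------------------------

#' Detected network bursts
#'
#' Result of network-burst detection on a \linkS4class{SpikeRecording}:
#' one row per burst plus the member spikes tagged by burst.
#'
#' @slot bursts data.frame with \code{burst_id}, \code{start_ms},
#'   \code{end_ms}, \code{duration_ms}, \code{n_spikes},
#'   \code{n_electrodes}.
#' @slot spikes data.frame of member spikes with \code{burst_id},
#'   \code{electrode_id}, \code{time_ms}.
#' @slot layout electrode layout inherited from the recording.
#' @slot params list of the detection parameters
#'   (\code{minElectrodes}, \code{maxGapMs}).
#' @export
setClass("BurstSet",
  representation(bursts = "data.frame", spikes = "data.frame",
                 layout = "data.frame", params = "list"))

setValidity("BurstSet", function(object) {
  b <- object@bursts
  need <- c("burst_id", "start_ms", "end_ms", "duration_ms",
            "n_spikes", "n_electrodes")
  if (!all(need %in% names(b))) return("bursts table is missing columns")
  if (nrow(b)) {
    if (any(b$end_ms < b$start_ms)) return("burst end before start")
    if (any(abs(b$duration_ms - (b$end_ms - b$start_ms)) > 1e-9))
      return("duration_ms must equal end_ms - start_ms")
    me <- object@params$minElectrodes
    if (!is.null(me) && any(b$n_electrodes < me))
      return("a burst spans fewer electrodes than minElectrodes")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# NetworkMetrics
# ---------------------------------------------------------------------------

#' Summary statistics of a functional network
#'
#' The five connectivity characteristics of a reconstructed network plus
#' the percent-of-maximum connectivity: Nc, the number of functional
#' connections; Nn, the average number of connections per cell; S, the
#' average signal-propagation speed d_ij/|tau_ij| over lagged edges;
#' P, the mean lag-maximised correlation over all cell pairs; Pa, the
#' same mean restricted to spatially adjacent pairs; and the percentage
#' of the n(n-1)/2 possible connections that is realised.
#'
#' @slot nc number of edges.
#' @slot nn mean incident edges per cell.
#' @slot speedUmPerFrame mean d/|tau| in um/frame over edges with
#'   nonzero lag (NA when no such edge exists).
#' @slot speedUmPerS the same speed in um/s (NA when the frame rate is
#'   unknown).
#' @slot meanCorrelation mean lag-maximised correlation over all pairs.
#' @slot adjacentCorrelation mean lag-maximised correlation over
#'   spatially adjacent pairs (NA when none).
#' @slot pctMax 100 * nc / (n(n-1)/2).
#' @slot nCells number of cells entering the pair enumeration.
#' @slot nZeroLagExcluded edges excluded from the speed average because
#'   their optimal lag is zero.
#' @export
setClass("NetworkMetrics",
  representation(nc = "numeric", nn = "numeric",
                 speedUmPerFrame = "numeric", speedUmPerS = "numeric",
                 meanCorrelation = "numeric",
                 adjacentCorrelation = "numeric", pctMax = "numeric",
                 nCells = "numeric", nZeroLagExcluded = "numeric"))
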