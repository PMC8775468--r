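#' @describeIn TraceMatrix cells-by-frames intensity matrix.
#' @param x a \linkS4class{TraceMatrix}.
#' @export
setMethod("traces", "TraceMatrix", function(x)
  SummarizedExperiment::assay(x, "fluorescence"))

#' @describeIn TraceMatrix acquisition rate in frames/s.
#' @export
setMethod("frameRate", "TraceMatrix", function(x)
  S4Vectors::metadata(x)$frameRate)

#' @describeIn TraceMatrix cell identifiers.
#' @export
setMethod("cellIds", "TraceMatrix", function(x) rownames(x))

#' @describeIn TraceMatrix number of frames.
#' @export
setMethod("nFrames", "TraceMatrix", function(x) ncol(x))

#' Frame times in seconds
#' @param x a \linkS4class{TraceMatrix}.
#' @return numeric vector, one entry per frame, starting at 0.
#' @export
frameTimes <- function(x) (seq_len(nFrames(x)) - 1) / frameRate(x)

setMethod("show", "TraceMatrix", function(object) {
  cat(sprintf("TraceMatrix: %d cells x %d frames @ %g frames/s (%.1f min)\n",
              nrow(object), ncol(object), frameRate(object),
              ncol(object) / frameRate(object) / 60))
})

#' @describeIn CellMap cell identifiers.
#' @param x a \linkS4class{CellMap}.
#' @export
setMethod("cellIds", "CellMap", function(x) x@cells$cell_id)

#' Coerce a CellMap to its underlying data.frame
#' @param x a \linkS4class{CellMap}.
#' @param row.names,optional,... ignored; present for S3 consistency.
#' @return data.frame with cell_id, x_um, y_um, radius_um.
#' @export
as.data.frame.CellMap <- function(x, row.names = NULL,
                                  optional = FALSE, ...) x@cells

setMethod("length", "CellMap", function(x) nrow(x@cells))

setMethod("show", "CellMap", function(object) {
  d <- object@cells
  cat(sprintf("CellMap: %d cells", nrow(d)))
  if (nrow(d))
    cat(sprintf(", field [%.0f x %.0f] um, radii %.1f-%.1f um",
                max(d$x_um + d$radius_um), max(d$y_um + d$radius_um),
                min(d$radius_um), max(d$radius_um)))
  cat("\n")
})

#' @describeIn FunctionalNetwork edge table.
#' @param x a \linkS4class{FunctionalNetwork}.
#' @export
setMethod("networkEdges", "FunctionalNetwork", function(x) x@edges)

#' @describeIn FunctionalNetwork node table.
#' @export
setMethod("networkNodes", "FunctionalNetwork", function(x) x@nodes)

#' @describeIn FunctionalNetwork cell identifiers of the vertex set.
#' @export
setMethod("cellIds", "FunctionalNetwork", function(x) x@nodes$cell_id)

#' @describeIn FunctionalNetwork frames/s of the source recording.
#' @export
setMethod("frameRate", "FunctionalNetwork", function(x) x@frameRate)

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf(
    "FunctionalNetwork (%s): %d cells, %d edges (rho_thr = %s)\n",
    object@mode, nrow(object@nodes), nrow(object@edges),
    format(object@rhoThreshold)))
  if (object@mode == "directed" && nrow(object@edges)) {
    nz <- sum(!object@edges$directed)
    if (nz) cat(sprintf("  %d zero-lag pair(s) kept undirected\n", nz))
  }
})

#' Convert a FunctionalNetwork to an igraph graph
#'
#' Vertices carry coordinates (when known) and edges carry the
#' correlation weight, the lag in frames and the directed flag.
#'
#' @param x a \linkS4class{FunctionalNetwork}.
#' @return an \pkg{igraph} graph.
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "FunctionalNetwork"))
  v <- x@nodes
  v$name <- as.character(v$cell_id)
  e <- x@edges
  if (nrow(e)) {
    e$from <- as.character(e$from)
    e$to <- as.character(e$to)
  }
  igraph::graph_from_data_frame(
    d = e, directed = x@mode == "directed",
    vertices = v[, c("name", setdiff(names(v), "name")), drop = FALSE])
}

#' @describeIn SpikeRecording spike table, sorted by time.
#' @param x a \linkS4class{SpikeRecording}.
#' @export
setMethod("spikes", "SpikeRecording", function(x) x@spikes)

setMethod("length", "SpikeRecording", function(x) nrow(x@spikes))

setMethod("show", "SpikeRecording", function(object) {
  cat(sprintf("SpikeRecording: %d spikes on %d electrodes over %.1f min\n",
              nrow(object@spikes),
              length(unique(object@spikes$electrode_id)),
              object@durationMin))
})

#' @describeIn BurstSet burst table.
#' @param x a \linkS4class{BurstSet}.
#' @export
setMethod("bursts", "BurstSet", function(x) x@bursts)

#' @describeIn BurstSet member spikes tagged by burst.
#' @export
setMethod("spikes", "BurstSet", function(x) x@spikes)

setMethod("length", "BurstSet", function(x) nrow(x@bursts))

setMethod("show", "BurstSet", function(object) {
  cat(sprintf(
    "BurstSet: %d network bursts (>= %d electrodes, gap <= %g ms)\n",
    nrow(object@bursts), object@params$minElectrodes,
    object@params$maxGapMs))
})

setMethod("show", "NetworkMetrics", function(object) {
  cat("NetworkMetrics\n")
  cat(sprintf("  connections (Nc):          %g\n", object@nc))
  cat(sprintf("  connections per cell (Nn): %.3f\n", object@nn))
  cat(sprintf("  propagation speed:         %.3f um/frame (%s um/s)\n",
              object@speedUmPerFrame,
              ifelse(is.na(object@speedUmPerS), "NA",
                     sprintf("%.2f", object@speedUmPerS))))
  cat(sprintf("  mean correlation (P):      %.3f\n",
              object@meanCorrelation))
  cat(sprintf("  neighbour correlation (Pa): %.3f\n",
              object@adjacentCorrelation))
  cat(sprintf("  %% of max connections:      %.2f%%\n", object@pctMax))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d cells on %g x %g um, %d frames @ %g fps\n",
    object@nCells, object@fieldSize[1], object@fieldSize[2],
    object@nFrames, object@frameRate))
  cat(sprintf(
    "  transients: %.3g /min, %.3g s, amplitude %.3g (noise sd %.3g)\n",
    object@transientRate, object@transientDuration,
    object@transientAmplitude, object@noiseSd))
  cat(sprintf("  %d planted edge(s), inactive fraction %.2f, seed %d\n",
              nrow(object@plantedEdges), object@inactiveFraction,
              object@seed))
})

#' Coerce a NetworkMetrics object to a named list
#' @param x a \linkS4class{NetworkMetrics}.
#' @return plain named list of the metric values.
#' @export
metricsAsList <- function(x) {
  stopifnot(is(x, "NetworkMetrics"))
  list(nc = x@nc, nn = x@nn,
       speed_um_per_frame = x@speedUmPerFrame,
       speed_um_per_s = x@speedUmPerS,
       mean_correlation = x@meanCorrelation,
       adjacent_correlation = x@adjacentCorrelation,
       pct_max = x@pctMax, n_cells = x@nCells,
       n_zero_lag_excluded = x@nZeroLagExcluded)
}
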