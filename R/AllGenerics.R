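#' Fluorescence trace matrix accessor
#'
#' @param x a \linkS4class{TraceMatrix}.
#' @return numeric matrix, cells in rows, frames in columns.
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' Acquisition frame rate (frames/s)
#' @param x an object carrying a frame rate.
#' @return frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Cell identifiers
#' @param x an object holding cells.
#' @return character vector of cell ids.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Number of recorded frames
#' @param x an object holding a recording.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Edge table of a functional network
#' @param x a \linkS4class{FunctionalNetwork}.
#' @return data.frame of edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Node table of a functional network
#' @param x a \linkS4class{FunctionalNetwork}.
#' @return data.frame of nodes.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Detect calcium oscillations on fluorescence traces
#'
#' @param x a \linkS4class{TraceMatrix} or a single numeric trace.
#' @param ... passed to methods; see
#'   \code{\link{detectEvents,TraceMatrix-method}}.
#' @return data.frame of events (\code{cell_id}, \code{t_start},
#'   \code{t_end}, \code{peak_amplitude}).
#' @export
setGeneric("detectEvents", function(x, ...) standardGeneric("detectEvents"))

#' Detect network bursts in an MEA spike recording
#'
#' @param x a \linkS4class{SpikeRecording}.
#' @param ... passed to methods; see
#'   \code{\link{detectBursts,SpikeRecording-method}}.
#' @return a \linkS4class{BurstSet}.
#' @export
setGeneric("detectBursts", function(x, ...) standardGeneric("detectBursts"))

#' Burst table accessor
#' @param x a \linkS4class{BurstSet}.
#' @return data.frame, one row per detected burst.
#' @export
setGeneric("bursts", function(x) standardGeneric("bursts"))

#' Spike table accessor
#' @param x a \linkS4class{SpikeRecording} or \linkS4class{BurstSet}.
#' @return data.frame of spikes.
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
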