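# Diagnostic figures (base graphics): correlation vs distance,
# network graph over the cell field, and burst rasters.

#' Correlation-versus-distance scatter
#'
#' Plots the lag-maximised correlation of every cell pair against the
#' distance between the cell centroids, with spatially adjacent pairs
#' (somata in contact) highlighted in red and the significance
#' threshold as a dashed line.
#'
#' @param pairs pair table from \code{\link{pairwiseCorrelations}}.
#' @param cellMap a \linkS4class{CellMap}.
#' @param contactSlack adjacency slack (see
#'   \code{\link{adjacencyPairs}}).
#' @param rhoThreshold threshold line to draw.
#' @return invisibly, the data.frame that was plotted.
#' @export
plotCorrelationDistance <- function(pairs, cellMap, contactSlack = 1.2,
                                    rhoThreshold = 0.3) {
  d <- pairDistances(cellMap, pairs$i, pairs$j)
  adj <- adjacencyPairs(cellMap, contactSlack)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  isAdj <- key(pairs$i, pairs$j) %in% key(adj$i, adj$j)
  plot(pairs$rho_max, d, col = ifelse(isAdj, "red", "blue"),
       pch = 16, cex = 0.6,
       xlab = "lag-maximised correlation",
       ylab = "intercentroid distance (um)")
  abline(v = rhoThreshold, lty = 2)
  legend("topright", legend = c("adjacent", "distant"),
         col = c("red", "blue"), pch = 16, bty = "n")
  invisible(data.frame(rho_max = pairs$rho_max, d_um = d,
                       adjacent = isAdj))
}

#' Plot a functional network over the cell field
#'
#' Draws each cell at its centroid and each edge as a segment; directed
#' edges get arrows from the leading to the lagging cell.
#'
#' @param network a \linkS4class{FunctionalNetwork} whose nodes carry
#'   coordinates.
#' @param ... passed to \code{plot}.
#' @return invisibly NULL.
#' @export
plotNetwork <- function(network, ...) {
  v <- networkNodes(network)
  if (!all(c("x_um", "y_um") %in% names(v)))
    stop("network nodes carry no coordinates", call. = FALSE)
  e <- networkEdges(network)
  plot(v$x_um, v$y_um, pch = 16, cex = 0.8, asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  if (nrow(e)) {
    f <- match(e$from, v$cell_id); t <- match(e$to, v$cell_id)
    dir <- e$directed
    if (any(!dir))
      segments(v$x_um[f[!dir]], v$y_um[f[!dir]],
               v$x_um[t[!dir]], v$y_um[t[!dir]], col = "grey50")
    if (any(dir))
      arrows(v$x_um[f[dir]], v$y_um[f[dir]],
             v$x_um[t[dir]], v$y_um[t[dir]],
             length = 0.06, col = "grey30")
  }
  invisible(NULL)
}

#' Spike raster with detected network bursts
#'
#' One row per electrode; detected bursts are shaded.
#'
#' @param recording a \linkS4class{SpikeRecording}.
#' @param burstSet optional \linkS4class{BurstSet} to overlay.
#' @return invisibly NULL.
#' @export
plotBurstRaster <- function(recording, burstSet = NULL) {
  s <- spikes(recording)
  els <- sort(unique(s$electrode_id))
  plot(NA, xlim = c(0, recording@durationMin * 60000),
       ylim = c(0.5, length(els) + 0.5),
       xlab = "time (ms)", ylab = "electrode", yaxt = "n")
  axis(2, at = seq_along(els), labels = els, las = 1, cex.axis = 0.6)
  if (!is.null(burstSet)) {
    b <- bursts(burstSet)
    if (nrow(b))
      rect(b$start_ms, 0.5, b$end_ms, length(els) + 0.5,
           col = grDevices::adjustcolor("orange", 0.3), border = NA)
  }
  points(s$time_ms, match(s$electrode_id, els), pch = "|", cex = 0.4)
  invisible(NULL)
}
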