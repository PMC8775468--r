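# Whole-field movie analysis: significant spatio-temporal activity
# events, watershed splitting into cell regions, and the per-cell
# characteristics C (mean region intensity) and A (active pixel count).

# Active-voxel mask: a pixel-frame is active when its intensity exceeds
# that pixel's temporal mean + multiplier * temporal SD (per-pixel
# statistics, so uneven staining does not bias detection).
activeVoxelMask <- function(movie, pixelThresholdMultiplier) {
  d <- dim(movie)
  M <- matrix(movie, nrow = d[1])          # frames x (h*w)
  mu <- colMeans(M)
  sdv <- sqrt(pmax(colMeans(M * M) - mu^2, 0) * d[1] / max(d[1] - 1, 1))
  thr <- mu + pixelThresholdMultiplier * sdv
  active <- M > rep(thr, each = d[1])
  active[, sdv == 0] <- FALSE              # constant pixels never fire
  array(active, dim = d)
}

#' Find spatio-temporal activity events in a movie
#'
#' Considers the whole image plane at once: voxels (frame, row, col)
#' whose intensity exceeds their pixel's temporal mean plus
#' \code{pixelThresholdMultiplier} standard deviations are active;
#' active voxels are grouped into 26-connected components in (t, y, x)
#' (diagonal connectivity tolerates one-frame flicker), and components
#' smaller than \code{minVoxels} are dropped.
#'
#' @param movie numeric array [frames, height, width] (as produced by
#'   \code{\link{renderMovie}} or \code{\link{readMovie}}).
#' @param pixelThresholdMultiplier threshold in per-pixel temporal SDs.
#' @param minVoxels smallest component retained.
#' @return list of events, each a list with \code{voxels} (data.frame
#'   \code{frame}, \code{row}, \code{col}), \code{nVoxels} and
#'   \code{frameRange}; ordered by first frame. An all-constant movie
#'   yields an empty list.
#' @export
findActivityEvents <- function(movie, pixelThresholdMultiplier = 2,
                               minVoxels = 8L) {
  d <- dim(movie)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("movie must be a non-empty [frames, height, width] array",
         call. = FALSE)
  active <- activeVoxelMask(movie, pixelThresholdMultiplier)
  idx <- which(active)
  if (!length(idx)) return(list())
  # integer (t, y, x) coordinates of active voxels
  tco <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  yco <- rest %% d[2] + 1L
  xco <- rest %/% d[2] + 1L
  keyOf <- function(t, y, x)   # double-precision exact for desk-scale movies
    (as.numeric(x) * (d[2] + 2) + y) * (d[1] + 2) + t
  keys <- keyOf(tco, yco, xco)
  ord <- order(keys)
  keys <- keys[ord]
  vox <- data.frame(frame = tco[ord], row = yco[ord], col = xco[ord])
  # half of the 26 neighbourhood offsets (the other half is symmetric)
  offs <- expand.grid(dt = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[seq_len(13L), ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nk <- keyOf(vox$frame + offs$dt[k], vox$row + offs$dy[k],
                vox$col + offs$dx[k])
    m <- match(nk, keys)
    hit <- !is.na(m)
    if (any(hit))
      edges <- rbind(edges, cbind(which(hit), m[hit]))
  }
  g <- igraph::make_empty_graph(n = nrow(vox), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  events <- lapply(split(seq_len(nrow(vox)), comp), function(ii) {
    v <- vox[ii, , drop = FALSE]
    rownames(v) <- NULL
    list(voxels = v, nVoxels = nrow(v),
         frameRange = range(v$frame))
  })
  events <- events[vapply(events, function(e) e$nVoxels, 0) >= minVoxels]
  events <- events[order(vapply(events, function(e) e$frameRange[1], 0),
                         vapply(events, function(e) min(e$voxels$row), 0))]
  names(events) <- NULL
  events
}

#' Split a spatio-temporal event into cell regions by watershed
#'
#' Projects the event onto the image plane (maximum intensity over the
#' event's voxels per pixel), smooths the projection with a Gaussian
#' (sigma 2 px) to suppress spurious maxima, and applies a watershed
#' transform seeded at the projection's regional maxima. Every voxel of
#' the event is assigned to exactly one region (the region of its
#' pixel), so the regions partition the event. An event with a single
#' intensity maximum is returned unsplit.
#'
#' @param event one event from \code{\link{findActivityEvents}}.
#' @param movie the movie the event was found in.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param tolerance minimum intensity depth separating two regional
#'   maxima (watershed merge tolerance); default 10% of the projection
#'   maximum.
#' @param ext neighbourhood radius (px) used to identify unique maxima.
#' @return list of per-region voxel data.frames (columns \code{frame},
#'   \code{row}, \code{col}).
#' @export
splitEventByCells <- function(event, movie, sigma = 2,
                              tolerance = NULL, ext = 2L) {
  v <- event$voxels
  if (is.null(v) || !nrow(v)) stop("event is empty", call. = FALSE)
  d <- dim(movie)
  proj <- matrix(0, d[2], d[3])
  val <- movie[cbind(v$frame, v$row, v$col)]
  pix <- cbind(v$row, v$col)
  agg <- tapply(val, list((pix[, 2] - 1L) * d[2] + pix[, 1]), max)
  proj[as.integer(names(agg))] <- as.numeric(agg)
  footprint <- proj > 0 | matrix(FALSE, d[2], d[3])
  footprint[cbind(v$row, v$col)] <- TRUE
  # pad so the Gaussian window never exceeds tiny images
  sm <- EBImage::gblur(proj, sigma = sigma, boundary = "replicate")
  sm[!footprint] <- 0
  sm[footprint & sm <= 0] <- .Machine$double.eps
  if (is.null(tolerance)) tolerance <- 0.1 * max(sm)
  lab <- EBImage::watershed(sm, tolerance = tolerance, ext = ext)
  lab <- matrix(as.integer(lab), d[2], d[3])
  # safety net: any footprint pixel the flooding left unlabelled joins
  # the nearest labelled pixel
  un <- which(footprint & lab == 0L, arr.ind = TRUE)
  if (nrow(un)) {
    lb <- which(lab > 0L, arr.ind = TRUE)
    for (k in seq_len(nrow(un))) {
      dd <- (lb[, 1] - un[k, 1])^2 + (lb[, 2] - un[k, 2])^2
      lab[un[k, 1], un[k, 2]] <- lab[lb[which.min(dd), 1],
                                     lb[which.min(dd), 2]]
    }
  }
  regionOf <- lab[cbind(v$row, v$col)]
  out <- lapply(split(seq_len(nrow(v)), regionOf), function(ii) {
    r <- v[ii, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  names(out) <- NULL
  out
}

#' Extract per-cell signals C and A from segmented events
#'
#' Splits every event into cell regions, optionally links regions to a
#' known cell map (nearest centroid within one cell radius; unmatched
#' regions get synthetic ids), and computes for each cell the two
#' characteristics used for network inference: C, the per-frame mean
#' intensity over the cell's region pixels, and A, the per-frame count
#' of the region's voxels active in that frame (0 on frames outside any
#' event).
#'
#' @param events list from \code{\link{findActivityEvents}}.
#' @param movie the source movie.
#' @param cellMap optional \linkS4class{CellMap} for linking regions to
#'   known cells.
#' @param umPerPixel spatial scale used for the linking (defaults to the
#'   movie's \code{umPerPixel} attribute, else 1).
#' @param ... passed to \code{\link{splitEventByCells}}.
#' @return long data.frame (\code{frame}, \code{cell_id}, \code{C},
#'   \code{A}), one row per frame and cell, ordered by cell then frame.
#' @export
extractCellSignals <- function(events, movie, cellMap = NULL,
                               umPerPixel = NULL, ...) {
  d <- dim(movie)
  if (is.null(umPerPixel))
    umPerPixel <- attr(movie, "umPerPixel")
  if (is.null(umPerPixel)) umPerPixel <- 1
  regions <- list()
  for (e in events)
    regions <- c(regions, splitEventByCells(e, movie, ...))
  if (!length(regions))
    return(data.frame(frame = integer(0), cell_id = character(0),
                      C = numeric(0), A = integer(0)))
  # assign region -> cell id
  cm <- if (!is.null(cellMap)) as.data.frame(cellMap) else NULL
  regId <- character(length(regions))
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    # pixel centres sit at (index - 0.5) * umPerPixel
    cy <- (mean(r$row) - 0.5) * umPerPixel
    cx <- (mean(r$col) - 0.5) * umPerPixel
    id <- sprintf("region_%03d", k)
    if (!is.null(cm) && nrow(cm)) {
      dd <- sqrt((cm$x_um - cx)^2 + (cm$y_um - cy)^2)
      hit <- which.min(dd)
      # within one cell radius, or one pixel for sub-pixel somata
      if (dd[hit] <= max(cm$radius_um[hit], umPerPixel))
        id <- cm$cell_id[hit]
    }
    regId[k] <- id
  }
  ids <- unique(regId)
  out <- vector("list", length(ids))
  for (u in seq_along(ids)) {
    vv <- do.call(rbind, regions[regId == ids[u]])
    pix <- unique(vv[, c("row", "col")])
    # C: mean intensity over the cell's footprint, every frame
    flat <- matrix(movie, nrow = d[1])
    lin <- (pix$col - 1L) * d[2] + pix$row
    C <- rowMeans(flat[, lin, drop = FALSE])
    A <- tabulate(vv$frame, nbins = d[1])
    out[[u]] <- data.frame(frame = seq_len(d[1]), cell_id = ids[u],
                           C = C, A = A)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
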