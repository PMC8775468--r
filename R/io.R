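# Format round-tripping: traces and cell maps as CSV, movies as
# multi-page grayscale TIFF, spikes as CSV, networks as GraphML,
# summaries and provenance as JSON.

#' Write / read a trace matrix as CSV
#'
#' Frames as rows, cells as columns, header row of cell ids; numbers at
#' full precision so write-then-read is bitwise exact.
#'
#' @param x a \linkS4class{TraceMatrix}.
#' @param path output file.
#' @return \code{writeTraces} returns \code{path} invisibly;
#'   \code{readTraces} returns a \linkS4class{TraceMatrix}.
#' @export
writeTraces <- function(x, path) {
  stopifnot(is(x, "TraceMatrix"))
  m <- t(traces(x))
  df <- as.data.frame(m)
  names(df) <- cellIds(x)
  utils::write.csv(format(df, digits = 17, trim = TRUE,
                          scientific = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @param frameRate frames/s of the stored recording.
#' @export
readTraces <- function(path, frameRate) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric")
  TraceMatrix(as.matrix(df), frameRate = frameRate,
              cellIds = names(df))
}

#' Write / read a cell map as CSV
#' @param x a \linkS4class{CellMap}.
#' @param path file path.
#' @return \code{writeCellMap} returns \code{path} invisibly;
#'   \code{readCellMap} a \linkS4class{CellMap}.
#' @export
writeCellMap <- function(x, path) {
  stopifnot(is(x, "CellMap"))
  d <- as.data.frame(x)
  d[c("x_um", "y_um", "radius_um")] <-
    lapply(d[c("x_um", "y_um", "radius_um")], function(v)
      format(v, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellMap
#' @export
readCellMap <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(cell_id = "character"))
  CellMap(d)
}

#' Write / read a spike table as CSV
#' @param x a \linkS4class{SpikeRecording}.
#' @param path file path.
#' @return \code{writeSpikes} returns \code{path} invisibly;
#'   \code{readSpikes} a \linkS4class{SpikeRecording}.
#' @export
writeSpikes <- function(x, path) {
  stopifnot(is(x, "SpikeRecording"))
  s <- spikes(x)
  s$time_ms <- format(s$time_ms, digits = 17, trim = TRUE,
                      scientific = FALSE)
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpikes
#' @param durationMin recording duration in minutes.
#' @param layout optional electrode layout data.frame (or a path to a
#'   layout CSV with columns electrode_id, row, col).
#' @export
readSpikes <- function(path, durationMin, layout = NULL) {
  s <- utils::read.csv(path, check.names = FALSE)
  s$time_ms <- suppressWarnings(as.numeric(s$time_ms))
  bad <- which(!is.finite(s$time_ms))
  if (length(bad))
    stop(sprintf("malformed spike rows (non-numeric time_ms) at line(s) %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  if (is.character(layout) && length(layout) == 1L)
    layout <- utils::read.csv(layout, check.names = FALSE)
  SpikeRecording(s, durationMin, layout)
}

#' Write / read a fluorescence movie as multi-page grayscale TIFF
#'
#' Intensities are stored as 32-bit samples after division by
#' \code{dynamicRange} (the TIFF writer requires values in [0, 1]),
#' giving a quantisation step of \code{dynamicRange / (2^32 - 1)} --
#' about 1.5e-8 intensity units at the default range, orders of
#' magnitude below any fluorescence noise floor and far below the CSV
#' path, which is the bitwise-exact interchange format.
#'
#' @param movie numeric array [frames, height, width].
#' @param path file path.
#' @param dynamicRange intensity mapped to 1.0 in the file.
#' @return \code{writeMovie} returns \code{path} invisibly;
#'   \code{readMovie} the [frames, height, width] array.
#' @export
writeMovie <- function(movie, path, dynamicRange = 64) {
  d <- dim(movie)
  stopifnot(length(d) == 3L)
  if (any(movie < 0) || any(movie > dynamicRange))
    stop("movie intensities must lie in [0, dynamicRange]",
         call. = FALSE)
  pages <- lapply(seq_len(d[1]), function(f)
    matrix(movie[f, , ] / dynamicRange, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeMovie
#' @param frameRate optional frames/s recorded on the returned array.
#' @param umPerPixel optional spatial scale recorded on the array.
#' @export
readMovie <- function(path, dynamicRange = 64, frameRate = NULL,
                      umPerPixel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  movie <- array(0, dim = c(length(pages), d[1], d[2]))
  for (f in seq_along(pages)) movie[f, , ] <- pages[[f]] * dynamicRange
  if (!is.null(frameRate)) attr(movie, "frameRate") <- frameRate
  if (!is.null(umPerPixel)) attr(movie, "umPerPixel") <- umPerPixel
  movie
}

#' Write / read a functional network as GraphML
#'
#' Vertices carry coordinates, edges the correlation weight, lag and
#' directed flag; the threshold and mode travel as graph attributes.
#'
#' @param x a \linkS4class{FunctionalNetwork}.
#' @param path file path.
#' @return \code{writeNetworkGraphML} returns \code{path} invisibly;
#'   \code{readNetworkGraphML} a \linkS4class{FunctionalNetwork}.
#' @export
writeNetworkGraphML <- function(x, path) {
  g <- asIgraph(x)
  igraph::graph_attr(g, "rhoThreshold") <- x@rhoThreshold
  igraph::graph_attr(g, "mode") <- x@mode
  igraph::graph_attr(g, "frameRate") <- x@frameRate
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkGraphML
#' @export
readNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(cell_id = vd$name)
  for (extra in setdiff(names(vd), c("name", "id", "cell_id")))
    nodes[[extra]] <- vd[[extra]]
  if (nrow(ed)) {
    edges <- data.frame(from = ed$from, to = ed$to,
                        weight = ed$weight, lag = ed$lag,
                        directed = as.logical(ed$directed))
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), lag = numeric(0),
                        directed = logical(0))
  }
  FunctionalNetwork(
    nodes = nodes, edges = edges,
    rhoThreshold = igraph::graph_attr(g, "rhoThreshold"),
    mode = igraph::graph_attr(g, "mode"),
    frameRate = igraph::graph_attr(g, "frameRate"))
}

#' Write a deterministic JSON artifact
#'
#' Full-precision, auto-unboxed JSON: the same object always produces
#' byte-identical output, which makes pipeline runs comparable by
#' checksum.
#'
#' @param x list to serialise.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeJsonArtifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Provenance record for an output directory
#'
#' Captures the package version, the stage parameters and the checksums
#' of the stage inputs, so any artifact directory documents how to
#' reproduce itself. The timestamp is informational and deliberately
#' kept out of the analysis artifacts themselves.
#'
#' @param stage name of the pipeline stage.
#' @param params named list of stage parameters.
#' @param inputs character vector of input file paths (checksummed when
#'   they exist).
#' @param path output JSON path.
#' @return the record, invisibly.
#' @export
writeProvenance <- function(stage, params, inputs = character(0),
                            path) {
  sums <- vapply(inputs, function(f)
    if (file.exists(f))
      as.character(tools::md5sum(f)) else NA_character_,
    character(1))
  rec <- list(
    tool = "CalNet",
    version = as.character(utils::packageVersion("CalNet")),
    stage = stage,
    parameters = params,
    inputs = as.list(sums),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(rec)
}
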