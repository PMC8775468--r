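# Calcium-event detection on per-cell fluorescence traces and the three
# culture-level activity parameters (share of working cells, oscillation
# frequency, oscillation duration).

detectEventsCore <- function(x, frameRate, thresholdMultiplier,
                             minDurationS, deviationMode,
                             bridgeFrames) {
  if (length(x) < 3L)
    stop("trace must have at least 3 frames", call. = FALSE)
  if (!all(is.finite(x)))
    stop("trace contains non-finite values", call. = FALSE)
  assertScalarNumeric(thresholdMultiplier, "thresholdMultiplier",
                      positive = TRUE)
  dev <- stats::sd(x)
  if (deviationMode == "sem") dev <- dev / sqrt(length(x))
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      peak_amplitude = numeric(0))
  if (!is.finite(dev) || dev == 0) return(empty)  # constant trace
  thr <- mean(x) + thresholdMultiplier * dev
  half <- mean(x) + 0.5 * thresholdMultiplier * dev
  above <- x > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  # bridge brief sub-threshold dips that stay above half-threshold, so
  # a single noisy frame cannot split one oscillation in two
  if (bridgeFrames > 0L && length(starts) > 1L) {
    sep <- vapply(seq_len(length(starts) - 1L), function(g) {
      gap <- (ends[g] + 1L):(starts[g + 1L] - 1L)
      !(length(gap) <= bridgeFrames && all(x[gap] > half))
    }, logical(1))
    grp <- cumsum(c(TRUE, sep))
    starts <- as.integer(tapply(starts, grp, min))
    ends <- as.integer(tapply(ends, grp, max))
  }
  minFrames <- max(1L, as.integer(ceiling(minDurationS * frameRate)))
  long <- (ends - starts + 1L) >= minFrames
  starts <- starts[long]; ends <- ends[long]
  if (!length(starts)) return(empty)
  data.frame(
    start_frame = starts, end_frame = ends,
    t_start = (starts - 1) / frameRate, t_end = ends / frameRate,
    peak_amplitude = vapply(seq_along(starts), function(k)
      max(x[starts[k]:ends[k]]), numeric(1)))
}

#' @describeIn detectEvents detect oscillations on every cell of a
#'   trace matrix.
#'
#' A frame belongs to an oscillation when its fluorescence exceeds the
#' trace mean plus \code{thresholdMultiplier} times the trace deviation;
#' maximal runs of such frames form the events, with Tstart/Tend taken
#' from the first and last frame of the run. The threshold is one-sided
#' (above the mean only) because calcium transients are positive-going.
#' A constant trace has zero deviation and yields no events.
#'
#' Two guards make the run decomposition robust to frame noise: brief
#' sub-threshold dips (at most \code{bridgeFrames} frames, staying above
#' half the threshold excess) are bridged, so one noisy frame cannot
#' split an oscillation in two; and runs shorter than
#' \code{minDurationS} are discarded, which suppresses noise-driven
#' crossings on silent cells. The minimum is expressed in seconds so
#' that detection does not depend on the acquisition rate.
#'
#' @param x a \linkS4class{TraceMatrix} or a numeric trace.
#' @param thresholdMultiplier threshold in units of the trace deviation
#'   (default 1: one deviation above the mean).
#' @param minDurationS minimum event duration in seconds.
#' @param bridgeFrames longest sub-threshold dip (frames) bridged inside
#'   an event; dip frames must stay above half the threshold excess.
#' @param deviationMode \code{"sd"} (sample standard deviation of the
#'   trace, the default) or \code{"sem"} (standard error of the mean;
#'   note the SEM shrinks with recording length, so detection then
#'   depends on how long the recording is).
#' @export
setMethod("detectEvents", "TraceMatrix",
  function(x, thresholdMultiplier = 1, minDurationS = 4,
           deviationMode = c("sd", "sem"), bridgeFrames = 2L) {
    deviationMode <- match.arg(deviationMode)
    X <- traces(x)
    fr <- frameRate(x)
    out <- lapply(seq_len(nrow(X)), function(i) {
      ev <- detectEventsCore(X[i, ], fr, thresholdMultiplier,
                             minDurationS, deviationMode, bridgeFrames)
      if (nrow(ev)) cbind(cell_id = rownames(X)[i], ev) else NULL
    })
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out))
      return(data.frame(cell_id = character(0), start_frame = integer(0),
                        end_frame = integer(0), t_start = numeric(0),
                        t_end = numeric(0), peak_amplitude = numeric(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })

#' @describeIn detectEvents detect oscillations on a single numeric
#'   trace; requires \code{frameRate}.
#' @param frameRate frames/s of the single trace (numeric method only).
#' @export
setMethod("detectEvents", "numeric",
  function(x, frameRate, thresholdMultiplier = 1, minDurationS = 4,
           deviationMode = c("sd", "sem"), bridgeFrames = 2L) {
    deviationMode <- match.arg(deviationMode)
    assertScalarNumeric(frameRate, "frameRate", positive = TRUE)
    detectEventsCore(x, frameRate, thresholdMultiplier, minDurationS,
                     deviationMode, bridgeFrames)
  })

#' Summarise calcium activity over a culture
#'
#' Computes the three activity parameters of a recording: the share of
#' working cells (cells with at least one detected oscillation), the
#' mean oscillation frequency over active cells (events/min), and the
#' mean oscillation duration over all events (s).
#'
#' @param events event table as returned by \code{\link{detectEvents}}
#'   (needs \code{cell_id}, \code{t_start}, \code{t_end}).
#' @param nCells total number of cells in the field of view.
#' @param durationMin recording duration in minutes.
#' @return list with \code{shareActivePct}, \code{meanFrequencyPerMin}
#'   (NA when no cell is active), \code{meanDurationS} (NA when there
#'   are no events) and \code{perCellCounts} (named integer vector over
#'   active cells).
#' @examples
#' ev <- data.frame(cell_id = c("a", "a", "b"), t_start = c(0, 30, 5),
#'                  t_end = c(10, 42, 17))
#' summarizeActivity(ev, nCells = 4, durationMin = 2)
#' @export
summarizeActivity <- function(events, nCells, durationMin) {
  assertScalarNumeric(durationMin, "durationMin", positive = TRUE)
  if (nCells <= 0) stop("nCells must be >= 1", call. = FALSE)
  if (!nrow(events))
    return(list(shareActivePct = 0, meanFrequencyPerMin = NA_real_,
                meanDurationS = NA_real_,
                perCellCounts = integer(0)))
  counts <- table(events$cell_id)
  perCell <- stats::setNames(as.integer(counts), names(counts))
  nActive <- length(perCell)
  list(
    shareActivePct = 100 * nActive / nCells,
    meanFrequencyPerMin = mean(perCell / durationMin),
    meanDurationS = mean(events$t_end - events$t_start),
    perCellCounts = perCell)
}
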