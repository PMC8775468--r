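# MEA network-burst detection, burst statistics and activation patterns.

#' @describeIn detectBursts detect network bursts in a spike recording.
#'
#' Pools all spikes across electrodes in time order (simultaneous spikes
#' ordered by electrode id for determinism) and partitions them into
#' maximal runs in which every consecutive inter-spike interval is at
#' most \code{maxGapMs}. Runs that recruit at least
#' \code{minElectrodes} distinct electrodes (counted over the whole run)
#' are network bursts. Maximality guarantees that two detected bursts
#' are always separated by a gap exceeding \code{maxGapMs}, every spike
#' belongs to at most one burst, and bursts never overlap.
#'
#' @param x a \linkS4class{SpikeRecording}.
#' @param minElectrodes minimum number of distinct electrodes a run must
#'   recruit (default 4).
#' @param maxGapMs maximum tolerated gap between consecutive pooled
#'   spikes within a burst (default 100 ms).
#' @export
setMethod("detectBursts", "SpikeRecording",
  function(x, minElectrodes = 4L, maxGapMs = 100) {
    s <- spikes(x)
    emptyB <- data.frame(burst_id = integer(0), start_ms = numeric(0),
                         end_ms = numeric(0), duration_ms = numeric(0),
                         n_spikes = integer(0), n_electrodes = integer(0))
    emptyS <- data.frame(burst_id = integer(0), electrode_id = integer(0),
                         time_ms = numeric(0))
    if (!nrow(s))
      return(new("BurstSet", bursts = emptyB, spikes = emptyS,
                 layout = x@layout,
                 params = list(minElectrodes = minElectrodes,
                               maxGapMs = maxGapMs)))
    run <- cumsum(c(TRUE, diff(s$time_ms) > maxGapMs))
    bs <- list(); ms <- list(); bid <- 0L
    for (g in split(seq_len(nrow(s)), run)) {
      els <- unique(s$electrode_id[g])
      if (length(els) < minElectrodes) next
      bid <- bid + 1L
      tt <- s$time_ms[g]
      bs[[bid]] <- data.frame(
        burst_id = bid, start_ms = tt[1], end_ms = tt[length(tt)],
        duration_ms = tt[length(tt)] - tt[1], n_spikes = length(g),
        n_electrodes = length(els))
      ms[[bid]] <- data.frame(burst_id = bid,
                              electrode_id = s$electrode_id[g],
                              time_ms = tt)
    }
    new("BurstSet",
        bursts = if (bid) do.call(rbind, bs) else emptyB,
        spikes = if (bid) do.call(rbind, ms) else emptyS,
        layout = x@layout,
        params = list(minElectrodes = minElectrodes,
                      maxGapMs = maxGapMs))
  })

#' Summarise network-burst activity
#'
#' Burst rate normalised to a 10-minute record (partial records are
#' scaled), mean spikes per burst and mean burst duration.
#'
#' @param burstSet a \linkS4class{BurstSet}.
#' @param durationMin recording duration in minutes.
#' @return list with \code{burstsPer10Min}, \code{meanSpikesPerBurst}
#'   and \code{meanBurstDurationMs} (the means are NA when no burst was
#'   detected).
#' @export
summarizeBursts <- function(burstSet, durationMin) {
  assertScalarNumeric(durationMin, "durationMin", positive = TRUE)
  b <- bursts(burstSet)
  list(
    burstsPer10Min = 10 * nrow(b) / durationMin,
    meanSpikesPerBurst = if (nrow(b)) mean(b$n_spikes) else NA_real_,
    meanBurstDurationMs = if (nrow(b)) mean(b$duration_ms) else NA_real_)
}

#' Activation pattern of one network burst
#'
#' The propagation fingerprint of a burst: for every participating
#' electrode, the delay of its first spike from the burst start. Rows
#' follow the electrode layout order (row, then column) when a layout is
#' known, so patterns can be rendered as a colour map of the array.
#'
#' @param burstSet a \linkS4class{BurstSet}.
#' @param burstId which burst.
#' @return data.frame with \code{electrode_id} and \code{delay_ms}.
#' @export
activationPattern <- function(burstSet, burstId) {
  b <- bursts(burstSet)
  if (!burstId %in% b$burst_id) stop("no such burst", call. = FALSE)
  s <- spikes(burstSet)
  s <- s[s$burst_id == burstId, , drop = FALSE]
  first <- tapply(s$time_ms, s$electrode_id, min)
  res <- data.frame(electrode_id = as.integer(names(first)),
                    delay_ms = as.numeric(first) -
                      b$start_ms[b$burst_id == burstId])
  lay <- burstSet@layout
  if (nrow(lay)) {
    m <- match(res$electrode_id, lay$electrode_id)
    res <- res[order(lay$row[m], lay$col[m], res$electrode_id), ,
               drop = FALSE]
  } else res <- res[order(res$electrode_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
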