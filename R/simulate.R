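# Synthetic-data generator: cell fields, coupled calcium traces, movies
# and MEA spike trains with planted ground truth.

#' Template calcium transient
#'
#' Unimodal kernel normalised to peak 1 and spanning \code{nFramesKernel}
#' frames: a brief linear rise (5% of the duration), a sustained plateau,
#' and a sharp exponential tail. The plateau-dominated shape makes the
#' nominal duration and the duration measured by mean-plus-deviation
#' thresholding agree to within a few percent for thresholds anywhere
#' between 10% and 70% of the peak, so planted and detected durations are
#' directly comparable.
#'
#' @param nFramesKernel kernel length in frames (>= 3).
#' @return numeric vector of length \code{nFramesKernel} in [0, 1].
#' @examples
#' plot(transientKernel(25), type = "s")
#' @export
transientKernel <- function(nFramesKernel) {
  L <- max(3L, as.integer(round(nFramesKernel)))
  rise <- max(1L, round(0.05 * L))
  platEnd <- max(rise + 1L, round(0.95 * L))
  platEnd <- min(platEnd, L)
  tau <- max(0.4, 0.02 * L)
  k <- numeric(L)
  k[seq_len(rise)] <- seq_len(rise) / rise
  if (platEnd > rise) k[(rise + 1L):platEnd] <- 1
  if (platEnd < L) {
    dec <- (platEnd + 1L):L
    k[dec] <- exp(-(dec - platEnd) / tau)
  }
  k
}

#' Place cells on the field
#'
#' Draws \code{nCells} non-overlapping discs uniformly at random on the
#' field by hard-disc rejection sampling. Radii are uniform on 5-10 um
#' (soma scale). Fails with an informative error when the requested
#' density cannot be packed within a bounded number of attempts.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param maxAttempts rejection attempts allowed per cell.
#' @return a \linkS4class{CellMap}.
#' @examples
#' simulateCellMap(SimulationConfig(nCells = 20, seed = 7))
#' @export
simulateCellMap <- function(config, maxAttempts = 2000L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nCells
  fs <- config@fieldSize
  empty <- data.frame(cell_id = character(0), x_um = numeric(0),
                      y_um = numeric(0), radius_um = numeric(0))
  if (n == 0L) return(CellMap(empty))
  withSeed(deriveSeed(config@seed, "cellmap"), {
    radii <- stats::runif(n, 5, 10)
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(maxAttempts)) {
        x <- stats::runif(1, radii[i], fs[1] - radii[i])
        y <- stats::runif(1, radii[i], fs[2] - radii[i])
        if (i == 1L ||
            all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >
                (radii[seq_len(i - 1)] + radii[i])^2)) {
          xs[i] <- x; ys[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf(
          "could not place cell %d of %d after %d attempts: density too high",
          i, n, maxAttempts), call. = FALSE)
    }
    CellMap(data.frame(cell_id = paste0("cell_", seq_len(n)),
                       x_um = xs, y_um = ys, radius_um = radii))
  })
}

# Draw non-overlapping event start frames for one cell. Events must fit
# inside the recording and keep a minimum gap so that detected runs never
# merge.
drawEventStarts <- function(nFrames, ratePerMin, frameRate, kernelLen,
                            minGap = 4L) {
  durMin <- nFrames / frameRate / 60
  nEv <- stats::rpois(1L, ratePerMin * durMin)
  latest <- nFrames - kernelLen + 1L
  if (latest < 1L) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(nEv)) {
    for (a in 1:100) {
      s <- sample.int(latest, 1L)
      if (!length(starts) || all(abs(s - starts) >= kernelLen + minGap)) {
        starts <- c(starts, s)
        break
      }
    }
  }
  sort(starts)
}

#' Simulate coupled calcium traces with planted ground truth
#'
#' Each active cell fires spontaneous template transients at Poisson-timed
#' starts; for every planted edge (i -> j, lag tau, probability p) each
#' event of i is copied into j shifted by tau frames with probability p
#' and amplitude \code{couplingScale} times the source amplitude.
#' Coupled copies take precedence over the target's own activity: a copy
#' displaces any spontaneous event of the target it would overlap
#' (a driven cell is busy relaying), and is dropped only when it
#' collides with an earlier copy, so per-cell ground-truth events are
#' always disjoint and the recorded event list corresponds exactly to
#' the painted transients. Gaussian noise of sd \code{noiseSd} is added
#' last.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param cellMap optional pre-built \linkS4class{CellMap}; by default the
#'   map is generated from the same config (and is then identical to
#'   \code{simulateCellMap(config)}).
#' @return list with elements \code{traces} (a
#'   \linkS4class{TraceMatrix}), and \code{groundTruth}: a list with
#'   \code{cellMap}, \code{events} (data.frame \code{cell_id},
#'   \code{start_frame}, \code{end_frame}, \code{t_start}, \code{t_end},
#'   \code{origin}), \code{plantedNetwork} (a
#'   \linkS4class{FunctionalNetwork} of the planted edges), and
#'   \code{activeCells}.
#' @examples
#' sim <- simulateTraces(SimulationConfig(nCells = 5, nFrames = 300,
#'                                        seed = 3))
#' sim$traces
#' @export
simulateTraces <- function(config, cellMap = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(cellMap)) cellMap <- simulateCellMap(config)
  n <- config@nCells
  nf <- config@nFrames
  fr <- config@frameRate
  L <- max(3L, as.integer(round(config@transientDuration * fr)))
  kern <- transientKernel(L) * config@transientAmplitude
  ids <- cellIds(cellMap)
  if (n > 0L && length(ids) != n)
    stop("cellMap size does not match config nCells")

  values <- matrix(0, nrow = nf, ncol = n)
  evList <- vector("list", n)

  withSeed(deriveSeed(config@seed, "events"), {
    if (length(config@inactiveCells)) {
      inactive <- config@inactiveCells
    } else {
      nInactive <- round(config@inactiveFraction * n)
      inactive <- if (nInactive > 0L) sample.int(n, nInactive) else
        integer(0)
    }
    active <- setdiff(seq_len(n), inactive)
    for (i in active) {
      st <- drawEventStarts(nf, config@transientRate, fr, L)
      if (length(st))
        evList[[i]] <- data.frame(cell = i, start = st,
                                  end = st + L - 1L,
                                  origin = "spontaneous")
    }
    # coupled copies take precedence over the target's own activity: a
    # copy displaces any overlapping spontaneous event of the target
    # (driven cells are busy relaying), and only collides with an
    # earlier copy, in which case the later copy is dropped. Copies are
    # taken from the sources' spontaneous event lists.
    pe <- config@plantedEdges
    spontList <- evList
    for (r in seq_len(nrow(pe))) {
      src <- pe$from[r]; dst <- pe$to[r]
      lag <- as.integer(pe$lag[r]); p <- pe$prob[r]
      srcEv <- spontList[[src]]
      if (is.null(srcEv) || !nrow(srcEv)) next
      for (k in seq_len(nrow(srcEv))) {
        if (stats::runif(1) > p) next
        s <- srcEv$start[k] + lag
        if (s < 1L || s + L - 1L > nf) next
        tgt <- evList[[dst]]
        if (!is.null(tgt) && nrow(tgt)) {
          hits <- s <= tgt$end & (s + L - 1L) >= tgt$start
          if (any(hits & tgt$origin == "coupled")) next
          if (any(hits)) tgt <- tgt[!hits, , drop = FALSE]
        }
        evList[[dst]] <- rbind(tgt,
          data.frame(cell = dst, start = s, end = s + L - 1L,
                     origin = "coupled"))
      }
    }
    # paint events (coupled ones at couplingScale amplitude)
    for (i in seq_len(n)) {
      ev <- evList[[i]]
      if (is.null(ev) || !nrow(ev)) next
      ev <- ev[order(ev$start), , drop = FALSE]
      evList[[i]] <- ev
      for (k in seq_len(nrow(ev))) {
        idx <- ev$start[k]:ev$end[k]
        amp <- if (ev$origin[k] == "coupled") config@couplingScale else 1
        values[idx, i] <- values[idx, i] + kern * amp
      }
    }
  })
  if (config@noiseSd > 0)
    withSeed(deriveSeed(config@seed, "noise"), {
      values <- values + matrix(stats::rnorm(nf * n, 0, config@noiseSd),
                                nf, n)
    })

  events <- do.call(rbind, c(evList[!vapply(evList, is.null, TRUE)],
                             list(data.frame(cell = integer(0),
                                             start = integer(0),
                                             end = integer(0),
                                             origin = character(0)))))
  events <- data.frame(
    cell_id = if (nrow(events)) ids[events$cell] else character(0),
    start_frame = events$start, end_frame = events$end,
    t_start = (events$start - 1) / fr, t_end = events$end / fr,
    origin = events$origin)

  # the functional direction runs leader -> follower: a negative planted
  # lag means the nominal target fires first, so the truth edge is flipped
  pe <- config@plantedEdges
  planted <- FunctionalNetwork(
    nodes = as.data.frame(cellMap),
    edges = if (nrow(pe)) data.frame(
      from = ids[ifelse(pe$lag >= 0, pe$from, pe$to)],
      to = ids[ifelse(pe$lag >= 0, pe$to, pe$from)],
      weight = NA_real_,
      lag = abs(as.numeric(pe$lag)), directed = TRUE) else
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0), lag = numeric(0),
                 directed = logical(0)),
    rhoThreshold = NA_real_, mode = "directed", frameRate = fr)

  tm <- TraceMatrix(values, frameRate = fr, cellIds = ids)
  S4Vectors::metadata(tm)$config <- config
  activeCells <- sort(unique(events$cell_id[events$origin ==
                                              "spontaneous"]))
  list(traces = tm,
       groundTruth = list(cellMap = cellMap, events = events,
                          plantedNetwork = planted,
                          activeCells = activeCells))
}

#' Sample a random directed coupling network with bounded degrees
#'
#' Helper for building planted-network scenarios: samples
#' \code{nEdges} distinct directed edges among \code{nCells} cells with
#' per-cell out- and in-degree caps. Capping the out-degree limits the
#' number of common-source cell pairs, the main source of confounded
#' (non-causal) correlations in additively coupled traces.
#'
#' @param nCells number of cells.
#' @param nEdges number of directed edges to plant.
#' @param maxOutDegree,maxInDegree per-cell degree caps.
#' @param nSources when given, the graph is made feed-forward: edges
#'   run only from a random subset of \code{nSources} cells to the
#'   remaining cells. Marginal-correlation methods cannot separate a
#'   direct link from coupling induced by a source-to-source cascade,
#'   so feed-forward truths are the appropriate benchmark for them.
#' @param lagRange inclusive range of (positive) lag values in frames;
#'   the direction of each edge is encoded by its from/to ordering.
#' @param prob coupling probability assigned to every edge.
#' @param seed RNG seed.
#' @return data.frame with \code{from}, \code{to}, \code{lag},
#'   \code{prob} suitable for \code{plantedEdges}.
#' @export
plantRandomNetwork <- function(nCells, nEdges, maxOutDegree = 2L,
                               maxInDegree = 2L, lagRange = c(2L, 8L),
                               prob = 1, seed = 1L, nSources = NULL) {
  withSeed(deriveSeed(seed, "scenario"), {
    if (!is.null(nSources)) {
      srcPool <- sample.int(nCells, nSources)
      tgtPool <- setdiff(seq_len(nCells), srcPool)
    } else {
      srcPool <- tgtPool <- seq_len(nCells)
    }
    for (attempt in 1:50) {
      outd <- ind <- integer(nCells)
      have <- character(0)
      from <- to <- integer(0)
      ok <- TRUE
      for (k in seq_len(nEdges)) {
        tg <- tgtPool[ind[tgtPool] < maxInDegree]
        placed <- FALSE
        for (j in sample(tg)) {
          sr <- srcPool[outd[srcPool] < maxOutDegree]
          sr <- sr[sr != j &
                   !paste(sr, j) %in% have & !paste(j, sr) %in% have]
          if (!length(sr)) next
          i <- sr[sample.int(length(sr), 1L)]
          from <- c(from, i); to <- c(to, j)
          have <- c(have, paste(i, j))
          outd[i] <- outd[i] + 1L; ind[j] <- ind[j] + 1L
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        lag <- sample(seq.int(lagRange[1], lagRange[2]), nEdges,
                      replace = TRUE)
        return(data.frame(from = from, to = to, lag = lag,
                          prob = prob))
      }
    }
    stop("cannot plant the requested edges under the degree caps")
  })
}

#' Canonical edge-recovery benchmark configuration
#'
#' One fixed scenario for scoring directed-edge recovery against a
#' planted truth: 30 cells of which 10 are autonomously active hub
#' cells and 20 are passive followers, 40 feed-forward edges (out-degree
#' at most 4, in-degree at most 2) with transmission probability 0.6
#' and lags of 2-8 frames, 6-s transients at 1.34 events/min, a
#' 60-minute recording at 2 frames/s, and additive noise at one fifth
#' of the transient amplitude. Followers carry no independent pacemaker
#' activity, so the planted links are direct functional connections --
#' the quantity a marginal-correlation method can recover.
#'
#' @param seed RNG seed for both the planted graph and the recording.
#' @param nCells,nEdges,nSources scenario size.
#' @return list with \code{config} (a \linkS4class{SimulationConfig})
#'   and \code{edges} (the planted edge table).
#' @export
recoveryBenchmarkConfig <- function(seed, nCells = 30L, nEdges = 40L,
                                    nSources = 10L) {
  edges <- plantRandomNetwork(nCells, nEdges, maxOutDegree = 4L,
                              maxInDegree = 2L, lagRange = c(2L, 8L),
                              prob = 0.6, seed = seed,
                              nSources = nSources)
  cfg <- SimulationConfig(
    nCells = nCells, nFrames = 7200L, frameRate = 2,
    transientRate = 1.34, transientDuration = 6,
    transientAmplitude = 10, noiseSd = 2, couplingScale = 1,
    inactiveCells = setdiff(seq_len(nCells), unique(edges$from)),
    plantedEdges = edges, seed = seed)
  list(config = cfg, edges = edges)
}

#' Render traces as a synthetic fluorescence movie
#'
#' Paints each cell's disc at its current trace intensity on a dark
#' background; overlapping discs add. The output array is indexed
#' [frame, row, col].
#'
#' @param traceMatrix a \linkS4class{TraceMatrix}.
#' @param cellMap the matching \linkS4class{CellMap}.
#' @param imageShape c(height, width) in pixels.
#' @param umPerPixel spatial scale; every disc must fit inside the image
#'   at this scale.
#' @return numeric array [frames, height, width] with attributes
#'   \code{umPerPixel} and \code{frameRate}.
#' @export
renderMovie <- function(traceMatrix, cellMap, imageShape = c(64L, 64L),
                        umPerPixel = 20) {
  stopifnot(is(traceMatrix, "TraceMatrix"), is(cellMap, "CellMap"))
  if (any(imageShape < 1))
    stop("imageShape must be positive", call. = FALSE)
  h <- as.integer(imageShape[1]); w <- as.integer(imageShape[2])
  d <- as.data.frame(cellMap)
  X <- traces(traceMatrix)
  if (nrow(d) != nrow(X))
    stop("cellMap and traceMatrix disagree on the number of cells")
  nf <- ncol(X)
  cx <- d$x_um / umPerPixel
  cy <- d$y_um / umPerPixel
  cr <- d$radius_um / umPerPixel
  if (nrow(d) && (any(cx - cr < 0) || any(cx + cr > w) ||
                  any(cy - cr < 0) || any(cy + cr > h)))
    stop("cells do not fit inside the image at this um-per-pixel scale")
  flat <- matrix(0, nrow = nf, ncol = h * w)
  colIdx <- function(row, col) (col - 1L) * h + row
  for (i in seq_len(nrow(d))) {
    rows <- which(abs(seq_len(h) - 0.5 - cy[i]) <= cr[i])
    cols <- which(abs(seq_len(w) - 0.5 - cx[i]) <= cr[i])
    if (!length(rows) || !length(cols)) next
    g <- expand.grid(row = rows, col = cols)
    keep <- (g$row - 0.5 - cy[i])^2 + (g$col - 0.5 - cx[i])^2 <= cr[i]^2
    g <- g[keep, , drop = FALSE]
    if (!nrow(g)) next
    idx <- colIdx(g$row, g$col)
    flat[, idx] <- flat[, idx] + X[i, ]
  }
  movie <- array(flat, dim = c(nf, h, w))
  attr(movie, "umPerPixel") <- umPerPixel
  attr(movie, "frameRate") <- frameRate(traceMatrix)
  movie
}

#' Simulate an MEA spike recording with planted network bursts
#'
#' Background activity is homogeneous Poisson per electrode; planted
#' bursts place \code{spikesPerElectrode} spikes on each of
#' \code{nElectrodesPerBurst} electrodes, with electrodes activated in
#' sequence every \code{spacingMs} (the planted propagation offset) and
#' a small uniform jitter on every spike. The constructed burst is
#' validated against the detector's gap contract: if jitter could push a
#' consecutive-spike gap to \code{maxGapMs} or more, generation aborts.
#'
#' @param nElectrodes electrodes on the array.
#' @param durationMin recording length in minutes.
#' @param burstStartsMs planted burst start times (ms). Defaults to
#'   regular spacing of \code{nBursts} bursts.
#' @param nBursts used when \code{burstStartsMs} is NULL.
#' @param nElectrodesPerBurst electrodes recruited per burst.
#' @param spikesPerElectrode spikes each recruited electrode fires.
#' @param spacingMs activation offset between successive electrodes (ms).
#' @param intraMs interval between successive spikes on one electrode (ms).
#' @param jitterMs half-width of the uniform jitter on each spike (ms).
#' @param backgroundRate background rate per electrode (spikes/s).
#' @param maxGapMs gap contract the planted bursts must respect.
#' @param seed RNG seed.
#' @return list with \code{recording} (a \linkS4class{SpikeRecording})
#'   and \code{plantedBursts} (data.frame \code{burst_id},
#'   \code{start_ms}, \code{end_ms}, \code{n_spikes},
#'   \code{n_electrodes}).
#' @examples
#' sim <- simulateSpikes(nBursts = 5, durationMin = 2, seed = 2)
#' sim$plantedBursts
#' @export
simulateSpikes <- function(nElectrodes = 15L, durationMin = 10,
                           burstStartsMs = NULL, nBursts = 36L,
                           nElectrodesPerBurst = 6L,
                           spikesPerElectrode = 15L, spacingMs = 10,
                           intraMs = 5, jitterMs = 1,
                           backgroundRate = 0.1, maxGapMs = 100,
                           seed = 1L) {
  assertScalarNumeric(durationMin, "durationMin", positive = TRUE)
  if (nElectrodesPerBurst > nElectrodes)
    stop("nElectrodesPerBurst exceeds nElectrodes", call. = FALSE)
  durMs <- durationMin * 60000
  # burst span: last electrode starts at (m-1)*spacing, fires s spikes
  span <- (nElectrodesPerBurst - 1) * spacingMs +
    (spikesPerElectrode - 1) * intraMs + 2 * jitterMs
  if (2 * jitterMs + max(spacingMs, intraMs) >= maxGapMs)
    stop("jitter/spacing would violate the burst gap contract",
         call. = FALSE)
  if (is.null(burstStartsMs)) {
    if (nBursts > 0) {
      gap <- durMs / nBursts
      if (gap < span + 2 * maxGapMs)
        stop("bursts too dense for the recording length", call. = FALSE)
      burstStartsMs <- (seq_len(nBursts) - 0.5) * gap
    } else burstStartsMs <- numeric(0)
  }
  withSeed(deriveSeed(seed, "spikes"), {
    sp <- data.frame(electrode_id = integer(0), time_ms = numeric(0))
    planted <- data.frame(burst_id = integer(0), start_ms = numeric(0),
                          end_ms = numeric(0), n_spikes = integer(0),
                          n_electrodes = integer(0))
    for (b in seq_along(burstStartsMs)) {
      els <- sample.int(nElectrodes, nElectrodesPerBurst)
      ts <- numeric(0); es <- integer(0)
      for (m in seq_along(els)) {
        base <- burstStartsMs[b] + (m - 1) * spacingMs +
          (seq_len(spikesPerElectrode) - 1) * intraMs
        jit <- stats::runif(spikesPerElectrode, -jitterMs, jitterMs)
        tt <- base + jit
        if (m == 1L) tt[1] <- burstStartsMs[b]  # anchor the burst start
        ts <- c(ts, tt); es <- c(es, rep(els[m], spikesPerElectrode))
      }
      o <- order(ts)
      ts <- ts[o]; es <- es[o]
      if (length(ts) > 1 && any(diff(ts) >= maxGapMs))
        stop("planted burst violates the gap contract", call. = FALSE)
      sp <- rbind(sp, data.frame(electrode_id = es, time_ms = ts))
      planted <- rbind(planted, data.frame(
        burst_id = b, start_ms = ts[1], end_ms = ts[length(ts)],
        n_spikes = length(ts), n_electrodes = length(unique(es))))
    }
    if (backgroundRate > 0) {
      for (e in seq_len(nElectrodes)) {
        nBg <- stats::rpois(1L, backgroundRate * durationMin * 60)
        if (nBg > 0)
          sp <- rbind(sp, data.frame(
            electrode_id = e, time_ms = stats::runif(nBg, 0, durMs)))
      }
    }
    layout <- data.frame(
      electrode_id = seq_len(nElectrodes),
      row = (seq_len(nElectrodes) - 1L) %/% ceiling(sqrt(nElectrodes)) + 1L,
      col = (seq_len(nElectrodes) - 1L) %% ceiling(sqrt(nElectrodes)) + 1L)
    list(recording = SpikeRecording(sp, durationMin, layout),
         plantedBursts = planted)
  })
}
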