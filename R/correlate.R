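# Lagged cross-correlation of detrended per-cell signals: the coupling
# measure from which functional networks are built.

#' Subtract a trailing moving average from a signal
#'
#' Removes slow baseline drift before correlation: every sample is
#' replaced by its deviation from the mean of the trailing window
#' [k - w, k] (truncated at the start of the recording, so the first
#' samples average over fewer frames).
#'
#' @param x numeric signal (one value per frame).
#' @param w window length in frames (>= 1; must be shorter than the
#'   signal).
#' @return detrended numeric vector of the same length, with the window
#'   stored in \code{attr(, "w")}.
#' @examples
#' detrendSignal(c(1, 2, 3), w = 1)   # 0, 0.5, 0.5
#' @export
detrendSignal <- function(x, w) {
  if (!all(is.finite(x)))
    stop("signal contains non-finite values", call. = FALSE)
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1", call. = FALSE)
  if (length(x) <= w)
    stop("signal must be longer than the window", call. = FALSE)
  out <- x - trailingMean(x, w)
  attr(out, "w") <- w
  out
}

#' Pearson correlation of two equal-length signals
#'
#' Standard centred Pearson coefficient. Zero-variance input yields NA
#' (an undefined correlation, excluded from graph construction) rather
#' than an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or NA when undefined.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("signals differ in length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("signals contain non-finite values", call. = FALSE)
  r <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(r)) NA_real_ else r
}

# Scan order 0, +1, -1, +2, -2, ...: ties between lags are resolved in
# favour of the smaller |tau|, positive before negative.
lagScanOrder <- function(W) {
  if (W == 0L) return(0L)
  c(0L, as.vector(rbind(seq_len(W), -seq_len(W))))
}

#' Maximum lagged correlation of a signal pair
#'
#' Computes the Pearson correlation of the overlapping segments of
#' \code{x} and \code{y} shifted by every integer lag tau in [-W, W]
#' (per-segment means, so the lag-0 value equals the plain Pearson
#' coefficient), and returns the maximum together with its lag.
#' Positive tau means \code{x} leads \code{y} (y is delayed), which
#' orients a directed edge x -> y. Ties are broken in favour of the
#' smallest |tau|, positive before negative.
#'
#' @param x,y numeric signals of equal length (already detrended).
#' @param W maximum |lag| in frames (>= 0); the overlap after the
#'   maximal shift must be at least 3 samples.
#' @return named numeric vector \code{c(rho_max =, tau =)}; both NA when
#'   the correlation is undefined at every lag.
#' @examples
#' x <- sin(seq(0, 20, length.out = 200))
#' laggedMaxCorrelation(x, c(rep(0, 3), x[1:197]), W = 10)  # tau = 3
#' @export
laggedMaxCorrelation <- function(x, y, W) {
  if (length(x) != length(y)) stop("signals differ in length",
                                   call. = FALSE)
  W <- as.integer(W)
  if (W < 0L) stop("W must be >= 0", call. = FALSE)
  n <- length(x)
  if (n - W < 3L)
    stop("overlap after the maximal shift must be >= 3 samples",
         call. = FALSE)
  best <- NA_real_; bestTau <- NA_integer_
  for (tau in lagScanOrder(W)) {
    if (tau >= 0L) { xs <- x[seq_len(n - tau)]; ys <- y[seq_len(n - tau) + tau] }
    else { xs <- x[seq_len(n + tau) - tau]; ys <- y[seq_len(n + tau)] }
    r <- suppressWarnings(stats::cor(xs, ys))
    if (is.finite(r) && (is.na(best) || r > best)) {
      best <- r; bestTau <- tau
    }
  }
  c(rho_max = best, tau = as.numeric(bestTau))
}

#' Lagged correlations for every cell pair
#'
#' Detrends every cell's signal with a trailing moving average of window
#' \code{w} frames, then computes, for every unordered pair, the
#' zero-lag Pearson correlation and the lag-maximised correlation over
#' integer lags in [-W, W]. Cells whose signal has zero variance are
#' excluded from the pair enumeration (their correlation is undefined);
#' the excluded ids are attached as \code{attr(, "excludedCells")}.
#'
#' All lags are computed with one matrix cross-product per lag, so the
#' cost is O(W n_cells^2 n_frames).
#'
#' @param x a \linkS4class{TraceMatrix}, or a numeric matrix with cells
#'   in rows and frames in columns (rownames as ids).
#' @param w detrending window in frames; defaults to the frames spanning
#'   10 s when \code{x} carries a frame rate (long enough to pass whole
#'   transients, short enough to track drift).
#' @param W maximum |lag| in frames.
#' @param detrend set FALSE if \code{x} is already detrended.
#' @return data.frame with one row per unordered pair: \code{i},
#'   \code{j}, \code{rho}, \code{rho_max}, \code{tau}. Positive tau
#'   means i leads j.
#' @export
pairwiseCorrelations <- function(x, w = NULL, W = 10L, detrend = TRUE) {
  if (is(x, "TraceMatrix")) {
    if (is.null(w)) w <- max(1L, as.integer(round(10 * frameRate(x))))
    X <- traces(x)
  } else {
    X <- as.matrix(x)
    if (is.null(w))
      stop("'w' must be given when x carries no frame rate",
           call. = FALSE)
    if (is.null(rownames(X)))
      rownames(X) <- paste0("cell_", seq_len(nrow(X)))
  }
  W <- as.integer(W)
  n <- ncol(X)
  if (n - W < 3L)
    stop("recording too short for the requested lag range",
         call. = FALSE)
  if (detrend)
    X <- t(apply(X, 1L, function(v) as.numeric(detrendSignal(v, w))))
  keep <- apply(X, 1L, function(v) stats::sd(v) > 0)
  excluded <- rownames(X)[!keep]
  if (length(excluded))
    message(sprintf("excluding %d zero-variance cell(s) from pairing",
                    length(excluded)))
  X <- X[keep, , drop = FALSE]
  nc <- nrow(X)
  ids <- rownames(X)
  emptyRes <- data.frame(i = character(0), j = character(0),
                         rho = numeric(0), rho_max = numeric(0),
                         tau = numeric(0))
  if (nc < 2L) {
    attr(emptyRes, "excludedCells") <- excluded
    attr(emptyRes, "w") <- w
    attr(emptyRes, "W") <- W
    return(emptyRes)
  }
  # rho matrix for each non-negative lag; negative lags by transposition
  corAtLag <- function(tau) {
    A <- X[, seq_len(n - tau), drop = FALSE]
    B <- X[, seq_len(n - tau) + tau, drop = FALSE]
    A <- A - rowMeans(A); B <- B - rowMeans(B)
    sa <- sqrt(rowSums(A * A)); sb <- sqrt(rowSums(B * B))
    R <- tcrossprod(A, B) / outer(sa, sb)
    R[!is.finite(R)] <- NA_real_
    R
  }
  Rpos <- lapply(0:W, corAtLag)
  ut <- upper.tri(Rpos[[1]])
  pairIdx <- which(ut, arr.ind = TRUE)   # i < j
  scan <- lagScanOrder(W)
  M <- vapply(scan, function(tau) {
    R <- Rpos[[abs(tau) + 1L]]
    if (tau >= 0L) R[ut] else t(R)[ut]
  }, numeric(nrow(pairIdx)))
  M <- matrix(M, nrow = nrow(pairIdx))
  Mfill <- M
  Mfill[is.na(Mfill)] <- -Inf
  pick <- max.col(Mfill, ties.method = "first")
  rhoMax <- M[cbind(seq_len(nrow(M)), pick)]
  tau <- scan[pick]
  allNA <- !is.finite(Mfill[cbind(seq_len(nrow(M)), pick)])
  rhoMax[allNA] <- NA_real_
  tau[allNA] <- NA_integer_
  res <- data.frame(i = ids[pairIdx[, 1]], j = ids[pairIdx[, 2]],
                    rho = Rpos[[1]][ut], rho_max = rhoMax,
                    tau = as.numeric(tau))
  attr(res, "excludedCells") <- excluded
  attr(res, "w") <- w
  attr(res, "W") <- W
  res
}
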