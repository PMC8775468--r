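# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that library code never
#' perturbs user-level random streams.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-stream seed from a root seed
#'
#' One root seed governs a simulation; each stochastic stream (cell
#' placement, event timing, noise, spikes) draws from its own derived
#' seed so that stages can be re-run independently yet reproducibly.
#' Kept below 2^31 - 1 so it is always a valid R integer seed.
#' @noRd
deriveSeed <- function(root, stream) {
  offsets <- c(cellmap = 101L, events = 211L, noise = 307L,
               spikes = 401L, scenario = 503L)
  off <- offsets[[stream]]
  as.integer((as.double(root) * 7919 + off) %% 2147483647)
}

#' @noRd
assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Trailing moving average with window truncated at the recording start
#'
#' mean(x[max(1, k - w) : k]) for every k, computed with cumulative sums.
#' @noRd
trailingMean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - w, 1L)
  (cs - c(0, cs)[lo]) / (seq_len(n) - lo + 1L)
}
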