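# Independent naive-loop oracles. These deliberately share no code with
# the package implementation: plain loops and textbook formulas only.

oracleDetrend <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1, k - w)
    s <- 0
    for (m in lo:k) s <- s + x[m]
    out[k] <- x[k] - s / (k - lo + 1)
  }
  out
}

oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sxx <- syy <- 0
  for (k in seq_len(n)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    sxx <- sxx + (x[k] - mx)^2
    syy <- syy + (y[k] - my)^2
  }
  num / sqrt(sxx * syy)
}

# exhaustive scan over every shift in [-W, W]; ties broken like the
# implementation (smallest |tau|, positive first) so results are
# comparable on generic data
oracleLagScan <- function(x, y, W) {
  n <- length(x)
  best <- -Inf; bestTau <- NA
  taus <- c(0, as.vector(rbind(seq_len(W), -seq_len(W))))
  if (W == 0) taus <- 0
  for (tau in taus) {
    if (tau >= 0) { xs <- x[1:(n - tau)]; ys <- y[(1 + tau):n] }
    else { xs <- x[(1 - tau):n]; ys <- y[1:(n + tau)] }
    r <- oraclePearson(xs, ys)
    if (is.finite(r) && r > best) { best <- r; bestTau <- tau }
  }
  c(best, bestTau)
}

# breadth-first flood fill over active voxels, 26-connectivity
oracleFloodFill <- function(active) {
  d <- dim(active)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(active, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dt in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dt == 0 && dy == 0 && dx == 0) next
        t2 <- q[1] + dt; y2 <- q[2] + dy; x2 <- q[3] + dx
        if (t2 < 1 || t2 > d[1] || y2 < 1 || y2 > d[2] ||
            x2 < 1 || x2 > d[3]) next
        if (active[t2, y2, x2] && lab[t2, y2, x2] == 0L) {
          lab[t2, y2, x2] <- cur
          queue[[length(queue) + 1]] <- c(t2, y2, x2)
        }
      }
    }
  }
  lab
}

# canonical representation of an event list for comparison: sorted
# voxel key strings per component
voxelKeySet <- function(voxels) {
  sort(paste(voxels$frame, voxels$row, voxels$col))
}

edgeKeys <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
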