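# Graph construction from pairwise correlations, spatial adjacency, and
# the network summary statistics.

#' Build a functional network from pairwise correlations
#'
#' Undirected mode admits a pair as an edge when its zero-lag Pearson
#' correlation exceeds \code{rhoThreshold}. Directed mode uses the
#' lag-maximised correlation and orients the edge by the sign of the
#' optimal lag: tau > 0 means i leads, giving i -> j. A directed edge
#' requires a nonzero lag; pairs whose optimum sits exactly at tau = 0
#' are kept in the directed graph as undirected edges unless
#' \code{strictLag = TRUE} drops them.
#'
#' @param pairs data.frame from \code{\link{pairwiseCorrelations}}
#'   (columns \code{i}, \code{j}, \code{rho}, \code{rho_max},
#'   \code{tau}).
#' @param cellMap optional \linkS4class{CellMap} supplying vertex
#'   coordinates; its cells define the vertex set (otherwise the cells
#'   appearing in \code{pairs}).
#' @param rhoThreshold significance threshold on the correlation
#'   (default 0.3).
#' @param mode \code{"undirected"} or \code{"directed"}.
#' @param strictLag drop zero-lag pairs from the directed graph instead
#'   of keeping them undirected.
#' @param frameRate frames/s of the source recording, recorded on the
#'   network for speed conversion (NA if unknown).
#' @return a \linkS4class{FunctionalNetwork}.
#' @export
buildNetwork <- function(pairs, cellMap = NULL, rhoThreshold = 0.3,
                         mode = c("undirected", "directed"),
                         strictLag = FALSE, frameRate = NA_real_) {
  mode <- match.arg(mode)
  if (!is.null(cellMap)) {
    nodes <- as.data.frame(cellMap)
  } else {
    nodes <- data.frame(cell_id = sort(unique(c(pairs$i, pairs$j))))
  }
  if (mode == "undirected") {
    keep <- !is.na(pairs$rho) & pairs$rho > rhoThreshold
    sel <- pairs[keep, , drop = FALSE]
    edges <- data.frame(from = sel$i, to = sel$j, weight = sel$rho,
                        lag = rep(NA_real_, nrow(sel)),
                        directed = rep(FALSE, nrow(sel)))
  } else {
    keep <- !is.na(pairs$rho_max) & pairs$rho_max > rhoThreshold
    sel <- pairs[keep, , drop = FALSE]
    zero <- !is.na(sel$tau) & sel$tau == 0
    if (strictLag) {
      sel <- sel[!zero, , drop = FALSE]
      zero <- logical(nrow(sel))
    }
    from <- ifelse(sel$tau >= 0, sel$i, sel$j)
    to <- ifelse(sel$tau >= 0, sel$j, sel$i)
    edges <- data.frame(from = from, to = to, weight = sel$rho_max,
                        lag = abs(sel$tau), directed = !zero)
  }
  rownames(edges) <- NULL
  FunctionalNetwork(nodes = nodes, edges = edges,
                    rhoThreshold = rhoThreshold, mode = mode,
                    frameRate = frameRate)
}

#' Spatially adjacent cell pairs
#'
#' A pair of cells counts as adjacent (somata in direct contact) when
#' the distance between their centroids does not exceed
#' \code{contactSlack} times the sum of their radii. The default 20%
#' slack absorbs centroid and radius estimation error.
#'
#' @param cellMap a \linkS4class{CellMap}.
#' @param contactSlack dimensionless multiplier on the sum of radii.
#' @return data.frame of unordered pairs (\code{i}, \code{j}) with the
#'   centroid distance \code{d_um}.
#' @export
adjacencyPairs <- function(cellMap, contactSlack = 1.2) {
  stopifnot(is(cellMap, "CellMap"))
  d <- as.data.frame(cellMap)
  empty <- data.frame(i = character(0), j = character(0),
                      d_um = numeric(0))
  if (nrow(d) < 2L) return(empty)
  dm <- as.matrix(stats::dist(d[, c("x_um", "y_um")]))
  rsum <- outer(d$radius_um, d$radius_um, "+")
  adj <- dm <= contactSlack * rsum & upper.tri(dm)
  idx <- which(adj, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  data.frame(i = d$cell_id[idx[, 1]], j = d$cell_id[idx[, 2]],
             d_um = dm[idx])
}

# centroid distances for a set of (i, j) id pairs
pairDistances <- function(cellMap, i, j) {
  d <- as.data.frame(cellMap)
  xi <- d$x_um[match(i, d$cell_id)]; yi <- d$y_um[match(i, d$cell_id)]
  xj <- d$x_um[match(j, d$cell_id)]; yj <- d$y_um[match(j, d$cell_id)]
  sqrt((xi - xj)^2 + (yi - yj)^2)
}

#' Network summary statistics
#'
#' Computes the connectivity characteristics of a reconstructed
#' functional network: the number of functional connections Nc, the
#' average number of connections per cell Nn, the average
#' signal-propagation speed S (mean of d_ij / |tau_ij| over edges with
#' a nonzero lag; zero-lag edges are excluded from the average and
#' counted), the average network correlation P (mean lag-maximised
#' correlation over all pairs), the average correlation of spatially
#' adjacent pairs Pa (over adjacent pairs whether or not they form an
#' edge), and the percentage of the maximum possible n(n-1)/2
#' connections that is realised.
#'
#' @param network a \linkS4class{FunctionalNetwork}.
#' @param pairs the full pair table from
#'   \code{\link{pairwiseCorrelations}} (for P and Pa).
#' @param cellMap a \linkS4class{CellMap} (for distances and adjacency).
#' @param contactSlack passed to \code{\link{adjacencyPairs}}.
#' @return a \linkS4class{NetworkMetrics} object.
#' @export
networkMetrics <- function(network, pairs, cellMap,
                           contactSlack = 1.2) {
  stopifnot(is(network, "FunctionalNetwork"), is(cellMap, "CellMap"))
  n <- nrow(networkNodes(network))
  if (n < 2L)
    stop("metrics are undefined for networks with fewer than 2 cells",
         call. = FALSE)
  e <- networkEdges(network)
  nc <- nrow(e)
  deg <- table(factor(c(e$from, e$to),
                      levels = networkNodes(network)$cell_id))
  nn <- mean(as.numeric(deg))
  lagged <- e[!is.na(e$lag) & e$lag != 0, , drop = FALSE]
  nZero <- sum(!is.na(e$lag) & e$lag == 0)
  if (nrow(lagged)) {
    dists <- pairDistances(cellMap, lagged$from, lagged$to)
    sFrame <- mean(dists / abs(lagged$lag))
  } else sFrame <- NA_real_
  fr <- frameRate(network)
  sSec <- if (is.finite(fr)) sFrame * fr else NA_real_
  p <- mean(pairs$rho_max, na.rm = TRUE)
  adj <- adjacencyPairs(cellMap, contactSlack)
  if (nrow(adj)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(adj$i, adj$j), key(pairs$i, pairs$j))
    pa <- mean(pairs$rho_max[m], na.rm = TRUE)
  } else pa <- NA_real_
  pctMax <- 100 * nc / (n * (n - 1) / 2)
  new("NetworkMetrics", nc = as.numeric(nc), nn = nn,
      speedUmPerFrame = sFrame, speedUmPerS = sSec,
      meanCorrelation = p, adjacentCorrelation = pa, pctMax = pctMax,
      nCells = as.numeric(n), nZeroLagExcluded = as.numeric(nZero))
}

#' Compare a recovered network with a planted ground truth
#'
#' Scores directed edge recovery: an unordered pair counts as recovered
#' when it is connected in both networks; orientation is scored
#' separately as the fraction of recovered true edges whose direction
#' (lag sign) matches the planted one.
#'
#' @param recovered,truth \linkS4class{FunctionalNetwork}s.
#' @return list with \code{truePositives}, \code{falsePositives},
#'   \code{falseNegatives}, \code{precision}, \code{recall}, \code{f1}
#'   and \code{lagSignAccuracy}.
#' @export
edgeRecoveryStats <- function(recovered, truth) {
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  er <- networkEdges(recovered)
  et <- networkEdges(truth)
  kr <- key(er); kt <- key(et)
  tp <- sum(kt %in% kr)
  fp <- sum(!kr %in% kt)
  fn <- sum(!kt %in% kr)
  precision <- if (nrow(er)) tp / nrow(er) else NA_real_
  recall <- if (nrow(et)) tp / nrow(et) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  hit <- match(kt, kr)
  ok <- 0L; tot <- 0L
  for (k in seq_along(hit)) {
    if (is.na(hit[k])) next
    tot <- tot + 1L
    if (er$directed[hit[k]] &&
        er$from[hit[k]] == et$from[k] && er$to[hit[k]] == et$to[k])
      ok <- ok + 1L
  }
  list(truePositives = tp, falsePositives = fp, falseNegatives = fn,
       precision = precision, recall = recall, f1 = f1,
       lagSignAccuracy = if (tot) ok / tot else NA_real_)
}
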