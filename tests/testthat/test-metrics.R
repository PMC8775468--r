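# Spatial adjacency and the network summary statistics.

squareMap <- function(n, spacing = 100, radius = 8) {
  g <- expand.grid(x = seq_len(ceiling(sqrt(n))),
                   y = seq_len(ceiling(sqrt(n))))[seq_len(n), ]
  CellMap(data.frame(cell_id = paste0("c", seq_len(n)),
                     x_um = g$x * spacing, y_um = g$y * spacing,
                     radius_um = radius))
}

test_that("adjacency follows the contact-slack rule", {
  cm <- CellMap(data.frame(cell_id = c("a", "b", "c"),
                           x_um = c(0, 21, 300), y_um = 0,
                           radius_um = 10))
  # tangent-ish pair within slack; distant pair excluded
  adj <- adjacencyPairs(cm, contactSlack = 1.1)
  expect_equal(nrow(adj), 1)
  expect_setequal(paste(adj$i, adj$j), "a b")
  # distance of 3x the radii sum is never adjacent
  far <- CellMap(data.frame(cell_id = c("a", "b"), x_um = c(0, 60),
                            y_um = 0, radius_um = 10))
  expect_equal(nrow(adjacencyPairs(far, 1.2)), 0)
})

test_that("adjacency matches an exhaustive distance check on 50 cells", {
  cfg <- SimulationConfig(nCells = 50, fieldSize = c(600, 600), seed = 33)
  cm <- simulateCellMap(cfg)
  adj <- adjacencyPairs(cm, contactSlack = 1.5)
  d <- as.data.frame(cm)
  wi <- wj <- character(0)
  for (i in 1:49) for (j in (i + 1):50) {
    dist <- sqrt((d$x_um[i] - d$x_um[j])^2 + (d$y_um[i] - d$y_um[j])^2)
    if (dist <= 1.5 * (d$radius_um[i] + d$radius_um[j])) {
      wi <- c(wi, d$cell_id[i]); wj <- c(wj, d$cell_id[j])
    }
  }
  expect_setequal(edgeKeys(data.frame(from = adj$i, to = adj$j)),
                  edgeKeys(data.frame(from = wi, to = wj)))
})

test_that("complete and edgeless graphs give the textbook metrics", {
  cm <- squareMap(5)
  ids <- cellIds(cm)
  full <- t(combn(ids, 2))
  prs <- data.frame(i = full[, 1], j = full[, 2], rho = 0.9,
                    rho_max = 0.9, tau = 1)
  net <- buildNetwork(prs, cellMap = cm, rhoThreshold = 0.3,
                      mode = "undirected")
  m <- networkMetrics(net, prs, cm)
  expect_equal(m@nc, 10)
  expect_equal(m@nn, 4)
  expect_equal(m@pctMax, 100)
  expect_equal(m@meanCorrelation, 0.9)
  # handshake identity
  expect_equal(m@nn, 2 * m@nc / m@nCells)
  prs0 <- transform(prs, rho = 0.1, rho_max = 0.1)
  m0 <- networkMetrics(buildNetwork(prs0, cellMap = cm,
                                    rhoThreshold = 0.3), prs0, cm)
  expect_equal(m0@nc, 0)
  expect_equal(m0@pctMax, 0)
  tiny <- FunctionalNetwork(data.frame(cell_id = "c1"), prs[0, 1:2],
                            rhoThreshold = 0.3)
  expect_error(networkMetrics(tiny, prs,
    CellMap(data.frame(cell_id = "c1", x_um = 1, y_um = 1,
                       radius_um = 5))), "fewer than 2")
})

test_that("propagation speed is the mean of distance over lag", {
  cm <- CellMap(data.frame(cell_id = c("a", "b", "c"),
                           x_um = c(0, 100, 0), y_um = c(0, 0, 40),
                           radius_um = 10))
  prs <- data.frame(i = c("a", "a", "b"), j = c("b", "c", "c"),
                    rho = 0.5, rho_max = c(0.8, 0.9, 0.7),
                    tau = c(5, 0, -2))
  net <- buildNetwork(prs, cellMap = cm, rhoThreshold = 0.3,
                      mode = "directed", frameRate = 2)
  m <- networkMetrics(net, prs, cm)
  # edges: a->b (d=100, |tau|=5), c->b (d=sqrt(100^2+40^2), |tau|=2);
  # the zero-lag a-c edge is excluded from the speed average
  dcb <- sqrt(100^2 + 40^2)
  expect_equal(m@speedUmPerFrame, mean(c(100 / 5, dcb / 2)))
  expect_equal(m@speedUmPerS, 2 * m@speedUmPerFrame)
  expect_equal(m@nZeroLagExcluded, 1)
  # planted-network speed agrees with hand-computed ground truth
  bench <- recoveryBenchmarkConfig(2)
  sim <- simulateTraces(bench$config)
  tnet <- sim$groundTruth$plantedNetwork
  te <- networkEdges(tnet)
  cmap <- sim$groundTruth$cellMap
  d <- as.data.frame(cmap)
  byHand <- mean(vapply(seq_len(nrow(te)), function(k) {
    i <- match(te$from[k], d$cell_id); j <- match(te$to[k], d$cell_id)
    sqrt((d$x_um[i] - d$x_um[j])^2 + (d$y_um[i] - d$y_um[j])^2) /
      abs(te$lag[k])
  }, numeric(1)))
  fake <- data.frame(i = te$from, j = te$to, rho = 1, rho_max = 1,
                     tau = te$lag)
  mt <- networkMetrics(tnet, fake, cmap)
  expect_equal(mt@speedUmPerFrame, byHand, tolerance = 1e-9)
})

test_that("neighbour correlation averages adjacent pairs, not edges", {
  cm <- CellMap(data.frame(cell_id = c("a", "b", "c"),
                           x_um = c(0, 18, 500), y_um = 0,
                           radius_um = 10))
  # a-b adjacent with sub-threshold correlation: still enters Pa
  prs <- data.frame(i = c("a", "a", "b"), j = c("b", "c", "c"),
                    rho = c(0.1, 0.8, 0.7),
                    rho_max = c(0.1, 0.8, 0.7), tau = 1)
  net <- buildNetwork(prs, cellMap = cm, rhoThreshold = 0.3,
                      mode = "undirected")
  m <- networkMetrics(net, prs, cm)
  expect_equal(m@adjacentCorrelation, 0.1)
  expect_equal(m@meanCorrelation, mean(c(0.1, 0.8, 0.7)))
})

test_that("percent of maximum is invariant to cell relabelling", {
  cm <- squareMap(6)
  ids <- cellIds(cm)
  full <- t(combn(ids, 2))
  set.seed(12)
  prs <- data.frame(i = full[, 1], j = full[, 2],
                    rho = runif(nrow(full)), tau = 1)
  prs$rho_max <- prs$rho
  m1 <- networkMetrics(buildNetwork(prs, cellMap = cm), prs, cm)
  # relabel by permuting ids consistently
  perm <- setNames(sample(ids), ids)
  prs2 <- transform(prs, i = unname(perm[i]), j = unname(perm[j]))
  cm2 <- CellMap(transform(as.data.frame(cm),
                           cell_id = unname(perm[cell_id])))
  m2 <- networkMetrics(buildNetwork(prs2, cellMap = cm2), prs2, cm2)
  expect_equal(m1@pctMax, m2@pctMax)
  expect_equal(m1@nc, m2@nc)
})
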