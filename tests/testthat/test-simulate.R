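# Synthetic-data generator: determinism, packing, planted-event and
# planted-edge fidelity, movie rendering, spike planting.

test_that("cell maps are deterministic, non-overlapping and bounded", {
  cfg <- SimulationConfig(nCells = 50, fieldSize = c(1000, 1000),
                          seed = 7)
  m1 <- as.data.frame(simulateCellMap(cfg))
  m2 <- as.data.frame(simulateCellMap(cfg))
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 50)
  # exhaustive pairwise check: centre distance exceeds sum of radii
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt((m1$x_um[i] - m1$x_um[j])^2 + (m1$y_um[i] - m1$y_um[j])^2)
    expect_gt(d, m1$radius_um[i] + m1$radius_um[j])
  }
  expect_true(all(m1$x_um - m1$radius_um >= 0 &
                  m1$x_um + m1$radius_um <= 1000 &
                  m1$y_um - m1$radius_um >= 0 &
                  m1$y_um + m1$radius_um <= 1000))
  # degenerate input and infeasible packing
  expect_equal(length(simulateCellMap(SimulationConfig(nCells = 0))), 0)
  dense <- SimulationConfig(nCells = 200, fieldSize = c(60, 60))
  expect_error(simulateCellMap(dense, maxAttempts = 20L),
               "density too high")
})

test_that("identical configs give bit-identical traces and ground truth", {
  cfg <- SimulationConfig(nCells = 12, nFrames = 400, seed = 3,
    plantedEdges = data.frame(from = 1, to = 2, lag = 3, prob = 0.5))
  a <- simulateTraces(cfg)
  b <- simulateTraces(cfg)
  expect_identical(traces(a$traces), traces(b$traces))
  expect_identical(a$groundTruth$events, b$groundTruth$events)
})

test_that("a single noise-free event reproduces the template exactly", {
  cfg <- SimulationConfig(nCells = 1, nFrames = 200, frameRate = 2,
                          transientRate = 0.3, transientDuration = 10,
                          transientAmplitude = 5, noiseSd = 0,
                          inactiveFraction = 0, seed = 21)
  sim <- simulateTraces(cfg)
  ev <- sim$groundTruth$events
  x <- as.numeric(traces(sim$traces))
  kern <- transientKernel(20) * 5
  for (k in seq_len(nrow(ev)))
    expect_equal(x[ev$start_frame[k]:ev$end_frame[k]], kern)
  # frames outside events are exactly zero
  inEv <- unlist(mapply(seq, ev$start_frame, ev$end_frame,
                        SIMPLIFY = FALSE))
  expect_true(all(x[setdiff(seq_along(x), inEv)] == 0))
})

test_that("ground-truth events are disjoint, in-recording, and match traces", {
  cfg <- SimulationConfig(nCells = 20, nFrames = 600, seed = 5,
    plantedEdges = plantRandomNetwork(20, 15, seed = 5))
  sim <- simulateTraces(cfg)
  ev <- sim$groundTruth$events
  expect_true(all(ev$start_frame >= 1 & ev$end_frame <= 600))
  expect_true(all(ev$t_start < ev$t_end))
  for (cc in unique(ev$cell_id)) {
    e <- ev[ev$cell_id == cc, ]
    e <- e[order(e$start_frame), ]
    if (nrow(e) > 1)
      expect_true(all(e$start_frame[-1] > e$end_frame[-nrow(e)]))
  }
})

test_that("inactive_fraction = 1 gives pure noise and empty truth", {
  cfg <- SimulationConfig(nCells = 5, nFrames = 300, noiseSd = 1,
                          inactiveFraction = 1, seed = 2)
  sim <- simulateTraces(cfg)
  expect_equal(nrow(sim$groundTruth$events), 0)
  expect_equal(length(sim$groundTruth$activeCells), 0)
  expect_lt(max(abs(colMeans(t(traces(sim$traces))))), 1)
})

test_that("a noise-free planted edge is an exact lagged copy", {
  cfg <- SimulationConfig(nCells = 2, nFrames = 500, frameRate = 2,
    transientRate = 1, transientDuration = 6, transientAmplitude = 8,
    noiseSd = 0, inactiveCells = 2L,
    plantedEdges = data.frame(from = 1, to = 2, lag = 3, prob = 1),
    seed = 11)
  sim <- simulateTraces(cfg)
  X <- traces(sim$traces)
  ev2 <- sim$groundTruth$events
  ev2 <- ev2[ev2$cell_id == "cell_2", ]
  expect_true(all(ev2$origin == "coupled"))
  # target trace restricted to copied events equals the source delayed
  for (k in seq_len(nrow(ev2))) {
    idx <- ev2$start_frame[k]:ev2$end_frame[k]
    expect_equal(X["cell_2", idx], X["cell_1", idx - 3])
  }
  # exhaustive lag scan finds the planted lag
  lm <- laggedMaxCorrelation(as.numeric(detrendSignal(X[1, ], 20)),
                             as.numeric(detrendSignal(X[2, ], 20)), 10)
  expect_equal(unname(lm["tau"]), 3)
  expect_gt(lm["rho_max"], 0.999)
})

test_that("rendered movies conserve intensity and sum overlaps per pixel", {
  cm <- CellMap(data.frame(cell_id = c("a", "b"),
                           x_um = c(300, 400), y_um = c(300, 320),
                           radius_um = c(120, 120)))
  tm <- TraceMatrix(matrix(c(2, 0, 1, 3), nrow = 2,
                           dimnames = list(NULL, c("a", "b"))),
                    frameRate = 1)
  mv <- renderMovie(tm, cm, imageShape = c(64, 64), umPerPixel = 10)
  expect_equal(dim(mv), c(2, 64, 64))
  # per-pixel oracle: paint discs independently and add
  paint <- function(x, y, r, v) {
    out <- matrix(0, 64, 64)
    for (row in 1:64) for (col in 1:64)
      if ((row - 0.5 - y / 10)^2 + (col - 0.5 - x / 10)^2 <= (r / 10)^2)
        out[row, col] <- v
    out
  }
  for (f in 1:2) {
    expected <- paint(300, 300, 120, traces(tm)["a", f]) +
      paint(400, 320, 120, traces(tm)["b", f])
    expect_equal(mv[f, , ], expected)
  }
  # constant-intensity disc mean equals the trace value
  tm1 <- TraceMatrix(matrix(4, 3, 1, dimnames = list(NULL, "a")),
                     frameRate = 1)
  cm1 <- CellMap(data.frame(cell_id = "a", x_um = 300, y_um = 300,
                            radius_um = 100))
  mv1 <- renderMovie(tm1, cm1, c(64, 64), umPerPixel = 10)
  disc <- mv1[1, , ][mv1[1, , ] > 0]
  expect_equal(unique(disc), 4)
  # zero traces give all-zero frames; bad geometry errors
  tm0 <- TraceMatrix(matrix(0, 3, 1, dimnames = list(NULL, "a")),
                     frameRate = 1)
  expect_true(all(renderMovie(tm0, cm1, c(64, 64), 10) == 0))
  expect_error(renderMovie(tm1, cm1, c(-1, 64), 10), "positive")
  expect_error(renderMovie(tm1, cm1, c(16, 16), 10), "fit")
})

test_that("planted spike bursts respect the gap contract and determinism", {
  sim <- simulateSpikes(nElectrodes = 12, durationMin = 5, nBursts = 8,
                        backgroundRate = 0, seed = 9)
  sim2 <- simulateSpikes(nElectrodes = 12, durationMin = 5, nBursts = 8,
                         backgroundRate = 0, seed = 9)
  expect_identical(spikes(sim$recording), spikes(sim2$recording))
  expect_equal(nrow(sim$plantedBursts), 8)
  s <- spikes(sim$recording)
  for (b in seq_len(8)) {
    pb <- sim$plantedBursts[b, ]
    tt <- s$time_ms[s$time_ms >= pb$start_ms & s$time_ms <= pb$end_ms]
    expect_true(all(diff(tt) < 100))
    expect_equal(length(tt), pb$n_spikes)
  }
  # empty table when nothing is planted and background is zero
  e <- simulateSpikes(nBursts = 0, backgroundRate = 0, durationMin = 1)
  expect_equal(nrow(spikes(e$recording)), 0)
  # jitter that can break the contract is rejected up front
  expect_error(simulateSpikes(jitterMs = 60, spacingMs = 50),
               "gap contract")
})
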