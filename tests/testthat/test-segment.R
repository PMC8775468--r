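# Movie segmentation: active voxels, 3D connected components,
# watershed splitting, and the per-cell signals C and A.

blockMovie <- function(dims, blocks, value = 10) {
  mv <- array(0, dims)
  for (b in blocks)
    mv[b$frames, b$rows, b$cols] <- value
  # a touch of baseline variation so per-pixel SD is defined
  mv + array(rep(seq(0, 0.01, length.out = dims[1]), prod(dims[2:3])),
             dims)
}

gaussBlobMovie <- function(centers, dims = c(40, 40, 40), sigma = 2,
                           frames = 4:8, amp = 10) {
  mv <- array(0, dims)
  g <- expand.grid(row = seq_len(dims[2]), col = seq_len(dims[3]))
  img <- matrix(0, dims[2], dims[3])
  for (cc in centers)
    img <- img + amp * exp(-((g$row - cc[1])^2 + (g$col - cc[2])^2) /
                             (2 * sigma^2))
  img[img < 0.05 * amp] <- 0      # compact blob support
  for (f in frames) mv[f, , ] <- img
  mv
}

test_that("degenerate movies yield no events", {
  expect_equal(length(findActivityEvents(array(0, c(10, 8, 8)))), 0)
  expect_equal(length(findActivityEvents(array(5, c(10, 8, 8)))), 0)
  expect_error(findActivityEvents(matrix(0, 3, 3)), "frames, height")
})

test_that("a bright block is one event with the exact voxel count", {
  mv <- blockMovie(c(90, 20, 20),
                   list(list(frames = 11:20, rows = 6:10, cols = 6:10)))
  ev <- findActivityEvents(mv, pixelThresholdMultiplier = 2,
                           minVoxels = 8)
  expect_equal(length(ev), 1)
  expect_equal(ev[[1]]$nVoxels, 10 * 5 * 5)
  expect_equal(ev[[1]]$frameRange, c(11, 20))
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(41)
  for (rep in 1:3) {
    mv <- array(0, c(50, 15, 15))
    # random scattered boxes, each lit for 10% of the frames
    for (b in 1:4) {
      f0 <- sample(1:40, 1); r0 <- sample(1:10, 1); c0 <- sample(1:10, 1)
      mv[f0:(f0 + 4), r0:(r0 + 2), c0:(c0 + 2)] <- 10
    }
    mv <- mv + array(rep(seq(0, 0.01, length.out = 50), 225), dim(mv))
    ev <- findActivityEvents(mv, 2, minVoxels = 1)
    active <- array(FALSE, dim(mv))
    mu <- apply(mv, c(2, 3), mean); sdv <- apply(mv, c(2, 3), sd)
    for (f in 1:50) active[f, , ] <- mv[f, , ] > mu + 2 * sdv
    lab <- oracleFloodFill(active)
    expect_gte(max(lab), 1)            # the check is not vacuous
    expect_equal(length(ev), max(lab))
    oracleSets <- lapply(seq_len(max(lab)), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      sort(paste(idx[, 1], idx[, 2], idx[, 3]))
    })
    gotSets <- lapply(ev, function(e) voxelKeySet(e$voxels))
    expect_setequal(vapply(gotSets, paste, collapse = ";", ""),
                    vapply(oracleSets, paste, collapse = ";", ""))
  }
})

test_that("two separated blocks are distinct; touching blocks merge", {
  sep <- blockMovie(c(60, 20, 20),
                    list(list(frames = 3:6, rows = 2:5, cols = 2:5),
                         list(frames = 12:15, rows = 12:15,
                              cols = 12:15)))
  expect_equal(length(findActivityEvents(sep, 2, 1)), 2)
  touch <- blockMovie(c(60, 20, 20),
                      list(list(frames = 3:6, rows = 2:5, cols = 2:5),
                           list(frames = 7:10, rows = 6:9, cols = 6:9)))
  expect_equal(length(findActivityEvents(touch, 2, 1)), 1)
})

test_that("watershed splits overlapping blobs and conserves voxels", {
  mv <- gaussBlobMovie(list(c(15, 15), c(15, 24)))
  ev <- findActivityEvents(mv, 2, minVoxels = 8)
  expect_equal(length(ev), 1)   # blobs overlap into one event
  regions <- splitEventByCells(ev[[1]], mv)
  expect_equal(length(regions), 2)
  # partition: disjoint and union equals the event voxel set
  all <- do.call(rbind, regions)
  expect_equal(sort(voxelKeySet(all)), sort(voxelKeySet(ev[[1]]$voxels)))
  expect_equal(nrow(all), ev[[1]]$nVoxels)
  # a single blob stays unsplit
  mv1 <- gaussBlobMovie(list(c(20, 20)))
  ev1 <- findActivityEvents(mv1, 2, 8)
  expect_equal(length(splitEventByCells(ev1[[1]], mv1)), 1)
})

test_that("k well-separated blobs give k cell regions for k = 1..5", {
  layout <- list(c(8, 8), c(8, 30), c(30, 8), c(30, 30), c(19, 19))
  for (k in 1:5) {
    mv <- gaussBlobMovie(layout[seq_len(k)], sigma = 2)
    ev <- findActivityEvents(mv, 2, minVoxels = 8)
    regions <- list()
    for (e in ev) regions <- c(regions, splitEventByCells(e, mv))
    expect_equal(length(regions), k)
  }
})

test_that("C and A are exact on a painted region and conserve totals", {
  mv <- blockMovie(c(90, 20, 20),
                   list(list(frames = 11:20, rows = 6:10, cols = 6:10)),
                   value = 7)
  ev <- findActivityEvents(mv, 2, minVoxels = 1)
  sig <- extractCellSignals(ev, mv)
  expect_equal(length(unique(sig$cell_id)), 1)
  # A = 25 active pixels during the event, 0 elsewhere
  expect_equal(sig$A[sig$frame %in% 11:20], rep(25, 10))
  expect_equal(sig$A[!sig$frame %in% 11:20], rep(0, 80))
  # C equals the painted value during the event (baseline ramp is tiny)
  expect_equal(mean(sig$C[sig$frame %in% 11:20]), 7, tolerance = 0.01)
  # frame-wise sum of A over cells equals the total active voxel count
  mv2 <- blockMovie(c(80, 30, 30),
                    list(list(frames = 3:8, rows = 3:7, cols = 3:7),
                         list(frames = 10:18, rows = 20:26,
                              cols = 18:24)))
  ev2 <- findActivityEvents(mv2, 2, minVoxels = 1)
  sig2 <- extractCellSignals(ev2, mv2)
  sumA <- tapply(sig2$A, sig2$frame, sum)
  perFrame <- vapply(seq_len(80), function(f)
    sum(unlist(lapply(ev2, function(e) sum(e$voxels$frame == f)))),
    numeric(1))
  expect_equal(as.numeric(sumA), perFrame)
})

test_that("segmenting a rendered recording recovers the traces", {
  cfg <- SimulationConfig(nCells = 4, fieldSize = c(300, 300),
                          nFrames = 240, frameRate = 2,
                          transientRate = 1, transientDuration = 8,
                          transientAmplitude = 10, noiseSd = 0,
                          inactiveFraction = 0, seed = 55)
  sim <- simulateTraces(cfg)
  mv <- renderMovie(sim$traces, sim$groundTruth$cellMap,
                    imageShape = c(60, 60), umPerPixel = 5)
  ev <- findActivityEvents(mv, 2, minVoxels = 8)
  sig <- extractCellSignals(ev, mv, cellMap = sim$groundTruth$cellMap,
                            umPerPixel = 5)
  X <- traces(sim$traces)
  firing <- unique(sim$groundTruth$events$cell_id)
  hit <- 0
  for (cc in intersect(unique(sig$cell_id), firing)) {
    Cc <- sig$C[sig$cell_id == cc][order(sig$frame[sig$cell_id == cc])]
    if (stats::sd(Cc) > 0 &&
        stats::cor(Cc, X[cc, ]) > 0.95) hit <- hit + 1
  }
  # every cell that fired is recovered with r > 0.95
  expect_equal(hit, length(firing))
})
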