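# Calcium-event detection and the culture-level activity summary.

test_that("degenerate traces are handled: flat, short, non-finite", {
  expect_equal(nrow(detectEvents(rep(5, 100), frameRate = 2)), 0)
  expect_error(detectEvents(c(1, 2), frameRate = 2), "at least 3")
  expect_error(detectEvents(c(1, NA, 3, 4), frameRate = 2), "non-finite")
})

test_that("an injected plateau is detected with exact bounds", {
  set.seed(4)
  x <- rnorm(400)
  x[101:130] <- x[101:130] + 10   # 30-frame plateau at baseline + 10 sd
  ev <- detectEvents(x, frameRate = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 101)
  expect_equal(ev$end_frame, 130)
  expect_equal(ev$t_end - ev$t_start, 15)   # 30 frames at 2 fps
  expect_equal(ev$peak_amplitude, max(x[101:130]))
})

test_that("detection is invariant to affine rescaling of the trace", {
  set.seed(8)
  x <- rnorm(500)
  for (s in c(50, 120, 300)) x[s:(s + 19)] <- x[s:(s + 19)] + 8
  ev1 <- detectEvents(x, frameRate = 2)
  ev2 <- detectEvents(3.7 * x + 42, frameRate = 2)
  expect_equal(ev1[c("start_frame", "end_frame")],
               ev2[c("start_frame", "end_frame")])
})

test_that("raising the threshold never increases the event count", {
  # strict monotonicity is a property of the plain run decomposition,
  # so dip bridging (whose gate moves with the threshold) is disabled
  set.seed(15)
  x <- rnorm(600)
  for (s in seq(40, 560, by = 60)) x[s:(s + 24)] <- x[s:(s + 24)] + 6
  counts <- vapply(c(0.5, 1, 1.5, 2, 3, 5), function(k)
    nrow(detectEvents(x, frameRate = 2, thresholdMultiplier = k,
                      bridgeFrames = 0L)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events are disjoint, ordered, and complement the quiet frames", {
  sim <- simulateTraces(SimulationConfig(nCells = 10, nFrames = 800,
                                         seed = 13))
  ev <- detectEvents(sim$traces)
  for (cc in unique(ev$cell_id)) {
    e <- ev[ev$cell_id == cc, ]
    expect_true(all(diff(e$start_frame) > 0))
    expect_true(all(e$start_frame[-1] > e$end_frame[-nrow(e)]))
    # event frames and non-event frames partition the recording
    inEv <- unlist(mapply(seq, e$start_frame, e$end_frame,
                          SIMPLIFY = FALSE))
    expect_equal(length(inEv) + (800 - length(inEv)), 800)
    expect_false(anyDuplicated(inEv) > 0)
  }
})

test_that("detected events match the generator ground truth", {
  cfg <- SimulationConfig(nCells = 30, nFrames = 1200, frameRate = 2,
                          transientRate = 1.3, transientDuration = 12,
                          transientAmplitude = 10, noiseSd = 1,
                          inactiveFraction = 0, seed = 19)
  sim <- simulateTraces(cfg)
  ev <- detectEvents(sim$traces)
  gt <- sim$groundTruth$events
  # per-cell counts agree for almost every cell; starts within 1 frame
  agree <- 0
  for (cc in unique(gt$cell_id)) {
    g <- gt[gt$cell_id == cc, ]
    e <- ev[ev$cell_id == cc, ]
    if (nrow(e) == nrow(g)) {
      agree <- agree + 1
      expect_true(all(abs(e$start_frame - g$start_frame) <= 1))
    }
  }
  expect_gte(agree / length(unique(gt$cell_id)), 0.95)
})

test_that("sem deviation mode detects more conservatively scaled events", {
  set.seed(30)
  x <- rnorm(300)
  x[100:120] <- x[100:120] + 3
  # SEM threshold is far lower than SD threshold, so the run is longer
  evSd <- detectEvents(x, frameRate = 2, deviationMode = "sd")
  evSem <- detectEvents(x, frameRate = 2, deviationMode = "sem")
  expect_gte(sum(evSem$t_end - evSem$t_start),
             sum(evSd$t_end - evSd$t_start))
})

test_that("activity summary arithmetic matches its definition", {
  ev <- data.frame(
    cell_id = rep(c("a", "b", "c"), each = 2),
    t_start = c(0, 30, 10, 50, 5, 70),
    t_end = c(12, 42, 22, 62, 17, 82))
  s <- summarizeActivity(ev, nCells = 4, durationMin = 2)
  expect_equal(s$shareActivePct, 75)
  expect_equal(s$meanFrequencyPerMin, 1)   # 2 events / 2 min each
  expect_equal(s$meanDurationS, 12)
  # no events
  s0 <- summarizeActivity(ev[0, ], nCells = 10, durationMin = 2)
  expect_equal(s0$shareActivePct, 0)
  expect_true(is.na(s0$meanDurationS))
  expect_error(summarizeActivity(ev, nCells = 0, durationMin = 2))
  expect_error(summarizeActivity(ev, nCells = 4, durationMin = 0))
})

test_that("estimated frequency agrees with the generator rate", {
  cfg <- SimulationConfig(nCells = 200, nFrames = 1200, frameRate = 2,
                          transientRate = 1.3, transientDuration = 12,
                          transientAmplitude = 10, noiseSd = 1,
                          inactiveFraction = 0, seed = 77)
  sim <- simulateTraces(cfg)
  gt <- sim$groundTruth$events
  counts <- table(gt$cell_id)
  est <- mean(counts) / 10
  # planted rate is thinned slightly by the non-overlap constraint;
  # 3 SE of the Poisson mean is the agreed band
  se <- sd(counts / 10) / sqrt(length(counts))
  expect_lt(abs(est - 1.3), 3 * se + 0.13)
})
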