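test_that("derivative is the fs-scaled forward difference", {
  expect_equal(pulse_derivative(pulse_series(c(0, 1, 2, 3), fs = 1)), c(1, 1, 1))
  expect_equal(pulse_derivative(pulse_series(rep(2, 10), fs = 50)), rep(0, 9))
  expect_equal(pulse_derivative(pulse_series(c(0, 2, 1), fs = 10)), c(20, -10))
})

test_that("segmentation cuts at the upstroke feet, independent of threshold", {
  clean <- fixture_train()   # 75 cycles of 0.8 s = 60 s
  cuts <- lapply(seq(0.1, 0.9, by = 0.1), function(thr)
    segment_at_threshold(clean, thr)$cut_points)
  # single dominant derivative lobe per beat: every threshold sees the same feet
  for (k in 2:9) expect_identical(cuts[[k]], cuts[[1]])
  n_seg <- nrow(segment_at_threshold(clean, 0.5)$segments)
  expect_true(abs(n_seg - 74) <= 1)
  # consecutive cuts are exactly one period apart
  expect_true(all(diff(cuts[[1]]) == 80L))
})

test_that("degenerate signals give empty segmentations, not errors", {
  flat <- pulse_series(rep(1, 200), fs = 100)
  seg <- segment_at_threshold(flat, 0.5)
  expect_equal(nrow(seg$segments), 0L)
  ramp <- pulse_series(seq(0, 1, length.out = 50), fs = 100)
  expect_equal(nrow(segment_at_threshold(ramp, 0.5)$segments), 0L)
  expect_error(segment_at_threshold(flat, 1.2), "\\(0, 1\\)")
})

test_that("quality screen accepts pulse periods and rejects artefacts", {
  cyc <- fixture_cycle()
  expect_equal(assess_quality(cyc, fs = 100), "normal")

  # far outside the physiological cycle range
  expect_equal(assess_quality(cyc[1:20], fs = 100), "abnormal")

  # 10x amplitude spike: fails the range rule against the cohort median
  spiked <- cyc; spiked[30] <- 10
  expect_equal(assess_quality(spiked, fs = 100, context = list(median_range = 1)),
               "abnormal")

  # white-noise segment: incoherent slope directions
  set.seed(5)
  expect_equal(assess_quality(rnorm(80), fs = 100), "abnormal")

  expect_equal(assess_quality(rnorm(80), fs = 100, strategy = "none"), "normal")
  expect_equal(assess_quality(cyc, fs = 100,
                              strategy = function(s, fs, ctx) FALSE), "abnormal")
  expect_error(assess_quality(cyc, fs = 100, strategy = "mystery"), "unknown")
  expect_error(assess_quality(numeric(0), fs = 100), "empty")
})

test_that("threshold selection maximizes normal segments, ties to the smallest", {
  clean <- fixture_train()
  sel <- select_threshold(clean)
  expect_equal(sel$threshold, 0.1)          # all thresholds tie at 74
  expect_equal(sel$n_normal, 74L)

  # deterministic: same input, same segmentation
  expect_identical(select_threshold(clean), sel)

  # falling-edge bump crosses only the 0.1 threshold and splits cycles there
  noisy <- fixture_train(bump = TRUE)
  seln <- select_threshold(noisy)
  expect_gt(seln$threshold, 0.1)
  expect_equal(seln$n_normal, 74L)

  set.seed(1)
  wn <- pulse_series(rnorm(3000), fs = 100)
  expect_error(select_threshold(wn), "unusable signal")
})

test_that("expansion window arithmetic and boundary handling", {
  set.seed(9)
  x <- c(cumsum(rnorm(300)))
  s <- pulse_series(x - min(x) + 1, fs = 100)
  seg <- structure(list(threshold = 0.5, cut_points = c(101L, 181L),
                        segments = data.frame(start = 101L, end = 181L,
                                              normal = TRUE),
                        n_normal = 1L),
                   class = "prv_segmentation")
  ex <- expand_segments(s, seg, fraction = 0.5)
  expect_length(ex, 1L)
  e <- ex[[1L]]
  expect_length(e$samples, 160L)                       # 2 x core length
  expect_identical(e$samples, s$samples[61:220])       # window (60, 220) 0-based
  expect_equal(unname(e$core), c(41L, 121L))           # core (40, 120) in window
  expect_true(e$fiducial >= e$core[1] && e$fiducial < e$core[2])
  d <- diff(s$samples)
  expect_equal(d[e$fiducial + 60],                     # fiducial = core argmax
               max(d[101:179]))

  # fraction 0 reproduces the bare period
  e0 <- expand_segments(s, seg, fraction = 0)[[1L]]
  expect_identical(e0$samples, s$samples[101:180])

  # window leaving the recording is dropped
  seg$segments$start <- 5L; seg$segments$end <- 85L
  seg$cut_points <- c(5L, 85L)
  expect_length(expand_segments(s, seg, fraction = 0.5), 0L)
  expect_error(expand_segments(s, seg, fraction = -1), ">= 0")
})

test_that("expanded segments contain their core and its derivative maximum", {
  clean <- fixture_train()
  sel <- select_threshold(clean)
  ex <- expand_segments(clean, sel, fraction = 0.5)
  expect_gt(length(ex), 50L)
  d <- diff(clean$samples)
  for (e in ex[seq(1, length(ex), by = 10)]) {
    expect_true(e$core[1] >= 1 && e$core[2] <= length(e$samples) + 1)
    expect_true(e$fiducial >= e$core[1] && e$fiducial < e$core[2])
    core_d <- diff(e$samples)[e$core[1]:(e$core[2] - 2L)]
    expect_equal(diff(e$samples)[e$fiducial], max(core_d))
  }
})
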