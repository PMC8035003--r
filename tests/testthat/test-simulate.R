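test_that("synthetic template has pulse-like construction properties", {
  tpl <- synth_template()                  # 0.8 s at 500 Hz
  expect_length(tpl, 400L)
  expect_lt(which.max(tpl) / length(tpl), 0.4)        # systolic peak early
  expect_lt(which.max(diff(tpl)), which.max(tpl))     # steepest rise before peak
  expect_lt(tpl[1], 0.05 * max(tpl))                  # starts near baseline
  expect_lt(tpl[length(tpl)], 0.05 * max(tpl))        # ends near baseline

  expect_equal(synth_template(amplitudes = 3 * c(1, 0.4, 0.25)), 3 * tpl)

  expect_error(synth_template(centers = c(0.28, 0.5, 1.2)), "outside the period")
  expect_error(synth_template(centers = c(0.5, 0.45, 0.6)), "increasing")
  expect_error(synth_template(amplitudes = c(0.2, 1, 0.3)), "dominate")
  expect_error(synth_template(duration = -1), "> 0")
})

test_that("dicrotic notch detection finds the first post-systolic minimum", {
  tpl <- synth_template()
  notch <- detect_notch(tpl, 500)
  expect_gt(notch, which.max(tpl) / 500)
  expect_lt(notch, 0.8)
  j <- round(notch * 500)
  expect_true(tpl[j + 1] > tpl[j])   # a genuine local minimum

  # monotone decay after the peak: fall back to 0.35 of the period
  decay <- c(seq(0, 1, length.out = 20), exp(-seq(0, 5, length.out = 180)))
  expect_equal(detect_notch(decay, 250), 0.35 * 200 / 250)
})

test_that("diastole-only stretching preserves the systole bit for bit", {
  tpl <- synth_template(0.8, 500)
  expect_equal(stretch_diastole(tpl, 500, 0.8, systole_end = 0.3), tpl)

  longer <- stretch_diastole(tpl, 500, 1.0, systole_end = 0.3)
  expect_length(longer, 500L)
  expect_identical(longer[1:150], tpl[1:150])

  shorter <- stretch_diastole(tpl, 500, 0.5, systole_end = 0.3)
  expect_length(shorter, 250L)
  expect_identical(shorter[1:150], tpl[1:150])

  expect_error(stretch_diastole(tpl, 500, 0.25, systole_end = 0.3), "shorter")
  expect_error(stretch_diastole(tpl, 500, 1.0, systole_end = 0.9), "inside")

  expect_length(stretch_whole(tpl, 500, 0.65), 325L)
})

test_that("training set reproduces the prescribed cohort structure", {
  ts <- generate_training_set(6, 4, seed = 42, fs = 250)
  expect_length(ts, 24L)
  grp <- vapply(ts, `[[`, "", "group")
  expect_equal(sum(grp == "arrhythmia"), 12L)
  expect_equal(sum(grp == "control"), 12L)

  for (s in ts) {
    expect_length(s$deltas, 60L)
    expect_equal(s$durations, s$t_b + s$deltas)
    expect_true(s$t_b >= 0.6 && s$t_b <= 1.0)
    w <- if (s$group == "arrhythmia") 0.09 else 0.07
    expect_true(all(abs(s$deltas) <= w))
    expect_lt(max(s$durations) - min(s$durations), 2 * w)
    expect_equal(length(s$series$samples), sum(round(s$durations * 250)))
  }

  # bit-identical reproducibility under the same seed
  ts2 <- generate_training_set(6, 4, seed = 42, fs = 250)
  expect_identical(ts, ts2)
  ts3 <- generate_training_set(6, 4, seed = 43, fs = 250)
  expect_false(identical(ts[[1]]$series$samples, ts3[[1]]$series$samples))
})

test_that("every simulated cycle starts with the same systole", {
  ts <- generate_training_set(2, 2, seed = 7, fs = 250)
  for (s in ts) {
    ends <- cumsum(round(s$durations * 250))
    starts <- c(1, head(ends, -1) + 1)
    first <- s$series$samples[starts[1]:(starts[1] + 49)]
    for (k in 2:60)
      expect_identical(s$series$samples[starts[k]:(starts[k] + 49)], first)
  }
})

test_that("empirical jitter matches the prescribed uniform law", {
  ts <- generate_training_set(10, 10, seed = 99, fs = 250)
  arr <- unlist(lapply(ts[vapply(ts, `[[`, "", "group") == "arrhythmia"],
                       `[[`, "deltas"))
  ks <- suppressWarnings(stats::ks.test(arr, "punif", -0.09, 0.09))
  expect_gt(ks$p.value, 0.01)
  ctrl <- unlist(lapply(ts[vapply(ts, `[[`, "", "group") == "control"],
                        `[[`, "deltas"))
  expect_gt(suppressWarnings(stats::ks.test(ctrl, "punif", -0.07, 0.07))$p.value,
            0.01)
})

test_that("simulated rhythms order the PRV index as SR < AF", {
  sr <- measure_prv(simulate_rhythm("SR", n_beats = 30, fs = 250, seed = 3))
  af <- measure_prv(simulate_rhythm("AF", n_beats = 30, fs = 250, seed = 4))
  expect_gt(af$d_e, 2 * sr$d_e)
  expect_error(simulate_rhythm("VF"), "arg")

  # a fixture-calibrated cutoff separates the two rhythms end to end
  d_sr <- vapply(1:4, function(k)
    measure_prv(simulate_rhythm("SR", n_beats = 20, fs = 250, seed = k))$d_e, 0.0)
  d_af <- vapply(5:8, function(k)
    measure_prv(simulate_rhythm("AF", n_beats = 20, fs = 250, seed = k))$d_e, 0.0)
  cut <- (max(d_sr) + min(d_af)) / 2
  expect_true(all(!vapply(d_sr, detect_af, TRUE, threshold = cut)))
  expect_true(all(vapply(d_af, detect_af, TRUE, threshold = cut)))
})

test_that("premature contractions leave a bulge in the averaged diastole", {
  bulge_rise <- function(kind, seed) {
    s <- simulate_rhythm(kind, n_beats = 40, fs = 500, seed = seed)
    seg <- select_threshold(s)
    avg <- align_and_average(expand_segments(s, seg, 0.5), fs = 500)
    x <- avg$samples
    win <- x[(avg$fiducial + round(0.55 * 400)):
               min(length(x), avg$fiducial + round(0.85 * 400))]
    max(win - cummin(win)) / diff(range(x))
  }
  expect_gt(bulge_rise("PC", 5), 0.10)
  expect_lt(bulge_rise("SR", 5), 0.05)
})
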