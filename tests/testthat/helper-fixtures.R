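# Deterministic pulse-train fixtures for segmentation tests.
#
# One cycle is 80 samples at fs = 100 Hz (0.8 s): 50 samples of baseline,
# a 10-sample linear upstroke to 1, a 20-sample linear fall back to 0.
# The derivative has a single dominant positive lobe per cycle, so every
# trial threshold in (0, 1) yields identical cut points (at the upstroke
# feet).  With `bump = TRUE` a small 3-sample rise of slope 0.15 x max is
# inserted on the falling edge, which crosses only the 0.1 threshold and
# splits each cycle there into two fragments that fail the quality screen.
fixture_cycle <- function(bump = FALSE) {
  rise <- seq(0, 1, length.out = 11)[-1]
  if (!bump) {
    c(rep(0, 50), rise, seq(1, 0, length.out = 21)[-1])
  } else {
    fall1 <- 1 - 0.05 * (1:8)
    bmp <- 0.6 + 0.015 * (1:3)
    c(rep(0, 48), rise, fall1, bmp, seq(bmp[3], 0, length.out = 11)[-1])
  }
}

fixture_train <- function(n_cycles = 75, bump = FALSE, fs = 100) {
  pulse_series(rep(fixture_cycle(bump), n_cycles), fs = fs, id = "fixture")
}

# Noise-free simulated recording with an explicit cycle-duration sequence,
# built the same way as the training-set generator realizes one sample.
fixture_jittered_series <- function(durations, t_b = 0.8, fs = 500,
                                    template = synth_template(t_b, fs)) {
  notch <- detect_notch(template, fs)
  x <- unlist(lapply(durations, function(Ti)
    stretch_diastole(template, fs, Ti, systole_end = notch)))
  pulse_series(x, fs = fs, id = "jittered")
}

expanded_seg <- function(samples, fiducial, core = c(1L, length(samples) + 1L)) {
  structure(list(samples = as.numeric(samples), fiducial = as.integer(fiducial),
                 core = as.integer(core), source_period = 1L),
            class = "expanded_segment")
}
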