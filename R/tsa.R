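#' Construct an averaged waveform object
#'
#' Mostly for internal use and tests; [align_and_average()] is the normal
#' producer.  `fiducial` equals `left_extent + 1`.
#'
#' @param samples numeric vector.
#' @param fiducial 1-based index of the common alignment point.
#' @param n_averaged number of segments averaged.
#' @param counts per-sample count of contributing segments (defaults to
#'   full coverage).
#' @param fs sampling rate, if known.
#' @return an `averaged_waveform` object.
#' @export
averaged_waveform <- function(samples, fiducial = 1L,
                              n_averaged = 1L, counts = NULL, fs = NA_real_) {
  samples <- as.numeric(samples)
  fiducial <- as.integer(fiducial)
  stopifnot(length(samples) >= 1L, fiducial >= 1L, fiducial <= length(samples),
            n_averaged >= 1L)
  if (is.null(counts)) counts <- rep.int(as.integer(n_averaged), length(samples))
  structure(
    list(samples = samples, fiducial = fiducial,
         n_averaged = as.integer(n_averaged),
         left_extent = fiducial - 1L,
         right_extent = length(samples) - fiducial + 1L,
         counts = as.integer(counts), fs = fs),
    class = "averaged_waveform")
}

#' @export
print.averaged_waveform <- function(x, ...) {
  cat(sprintf("<averaged_waveform> %d samples, fiducial at %d, N = %d\n",
              length(x$samples), x$fiducial, x$n_averaged))
  invisible(x)
}

#' @export
length.averaged_waveform <- function(x) length(x$samples)

#' Fiducial-aligned time synchronous average
#'
#' Places every expanded segment with its fiducial at a common origin, in a
#' frame spanning the maximum left extent to the maximum right extent over
#' all segments, pads each segment with exact zeros outside its own extent,
#' and averages elementwise.  The denominator is N everywhere — zeros count
#' toward the mean — which is the literal per-beat ensemble mean
#' `X_a = (1/N) * sum(X_i)`; the resulting attenuation affects only the
#' frame tails where not all segments contribute, and the per-sample
#' contribution counts are kept so downstream steps can restrict themselves
#' to the fully covered region.
#'
#' @param segments non-empty list of `expanded_segment` objects (see
#'   [expand_segments()]).
#' @param fs sampling rate to record on the output, if known.
#' @return an [averaged_waveform()]; its `fiducial` sample equals the mean
#'   of the segments' fiducial samples.
#' @export
align_and_average <- function(segments, fs = NA_real_) {
  if (length(segments) == 0L) stop("no segments to average")
  lefts <- vapply(segments, function(s) s$fiducial - 1L, 0L)
  rights <- vapply(segments, function(s) length(s$samples) - s$fiducial + 1L, 0L)
  left <- max(lefts); right <- max(rights)
  len <- left + right
  acc <- numeric(len)
  cnt <- integer(len)
  for (s in segments) {
    off <- left - (s$fiducial - 1L)       # zero-based placement offset
    idx <- (off + 1L):(off + length(s$samples))
    acc[idx] <- acc[idx] + s$samples
    cnt[idx] <- cnt[idx] + 1L
  }
  averaged_waveform(acc / length(segments), fiducial = left + 1L,
                    n_averaged = length(segments), counts = cnt, fs = fs)
}

#' Single-period template by classic TSA
#'
#' Runs the full preprocessing chain with expansion fraction 0 (bare
#' periods), then averages: the classic use of time synchronous averaging to
#' recover one clean single-period pulse waveform from a noisy recording.
#'
#' @param series a [pulse_series()].
#' @param config a [prv_config()]; its `expansion_fraction` is ignored here.
#' @return an [averaged_waveform()] holding the one-period template.
#' @export
single_period_template <- function(series, config = prv_config()) {
  seg <- select_threshold(series, config)
  ex <- expand_segments(series, seg, fraction = 0)
  if (length(ex) == 0L) stop("no usable segments for template extraction")
  align_and_average(ex, fs = series$fs)
}
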