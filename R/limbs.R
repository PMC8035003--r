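#' Extract the two ascending limbs from an averaged waveform
#'
#' On the averaged two-period waveform, the first ascending limb runs from
#' the minimum preceding the first-half maximum up to that maximum (the
#' systolic upstroke of the sharply aligned first period).  The second
#' ascending limb starts at the minimum between the first-half maximum and
#' the second-half maximum and has the same length `n` — the upstroke of the
#' second period, smeared in proportion to the pulse rate variability.
#' Halves are halves of the frame, split at `floor(len / 2)`; non-unique
#' extrema resolve to the earliest index.
#'
#' By default the frame is first trimmed to the region where every segment
#' contributed (`trim = "coverage"`): in the zero-filled tails the ensemble
#' mean is pulled toward zero by the missing segments, which would otherwise
#' hijack the minima that anchor the limbs.  A plain numeric vector is
#' accepted and treated as fully covered.
#'
#' @param avg an [averaged_waveform()] or a numeric vector (length >= 4).
#' @param trim `"coverage"` (default) or `"none"`.
#' @return a `limb_pair`: numeric `first` and `second` of common length `n`,
#'   plus `anchor_indices` (starts of the two limbs in the frame supplied).
#' @export
extract_limbs <- function(avg, trim = c("coverage", "none")) {
  trim <- match.arg(trim)
  if (is.numeric(avg)) avg <- averaged_waveform(avg)
  stopifnot(inherits(avg, "averaged_waveform"))
  x <- avg$samples
  off <- 0L
  if (trim == "coverage" && any(avg$counts < avg$n_averaged)) {
    full <- which(avg$counts == avg$n_averaged)
    if (length(full) < 4L) stop("fully covered frame region is degenerate")
    off <- full[1L] - 1L
    x <- x[full[1L]:full[length(full)]]
  }
  len <- length(x)
  if (len < 4L) stop("averaged waveform too short for limb extraction")
  H <- len %/% 2L

  p1 <- which.max(x[1:H])
  m1 <- which.min(x[1:p1])
  n <- p1 - m1 + 1L
  if (n < 2L) stop("degenerate first limb: first-half maximum has no preceding rise")

  p2 <- H + which.max(x[(H + 1L):len])
  if (p2 - p1 < 2L) stop("degenerate second limb: no room between the half maxima")
  q <- p1 + which.min(x[(p1 + 1L):(p2 - 1L)])
  if (q + n - 1L > len) stop("degenerate second limb: frame too short")

  structure(
    list(first = x[m1:p1], second = x[q:(q + n - 1L)], n = n,
         anchor_indices = c(first = m1 + off, second = q + off)),
    class = "limb_pair")
}

#' @export
print.limb_pair <- function(x, ...) {
  cat(sprintf("<limb_pair> n = %d, anchors at %d / %d\n",
              x$n, x$anchor_indices[1L], x$anchor_indices[2L]))
  invisible(x)
}

#' Distance indexes between the two ascending limbs
#'
#' For limbs `X_f` and `X_s` of common length `n`:
#' \deqn{D_e = \sqrt{\sum_i (x_{fi} - x_{si})^2}, \quad
#'       D_m = \sum_i |x_{fi} - x_{si}|, \quad
#'       D_c = \frac{\sum_i x_{fi} x_{si}}
#'                  {\sqrt{\sum_i x_{fi}^2}\sqrt{\sum_i x_{si}^2}}.}
#' `d_c` is, despite its conventional "cosine distance" name, the cosine
#' similarity (identical limbs give 1); it is computed exactly as written.
#' An all-zero limb makes `d_c` undefined (`NaN`, with a warning).
#'
#' @param pair a `limb_pair` from [extract_limbs()], or a list/two vectors.
#' @param second when `pair` is a plain numeric vector, the second limb.
#' @return named list with `d_e`, `d_m`, `d_c`, `n`.
#' @export
limb_distances <- function(pair, second = NULL) {
  if (is.numeric(pair) && !is.null(second)) pair <- list(first = pair, second = second)
  xf <- as.numeric(pair$first); xs <- as.numeric(pair$second)
  if (length(xf) != length(xs)) stop("limbs must have equal length")
  n <- length(xf)
  if (n < 2L) stop("limbs must have length >= 2")
  diffv <- xf - xs
  d_e <- sqrt(sum(diffv^2))
  d_m <- sum(abs(diffv))
  nf <- sqrt(sum(xf^2)); ns <- sqrt(sum(xs^2))
  if (nf == 0 || ns == 0) {
    warning("all-zero limb: cosine index undefined")
    d_c <- NaN
  } else {
    d_c <- sum(xf * xs) / (nf * ns)
  }
  list(d_e = d_e, d_m = d_m, d_c = d_c, n = n)
}

#' Atrial fibrillation decision
#'
#' AF is called when the Euclidean limb distance strictly exceeds the
#' threshold; the boundary value is classified non-AF.  `d_e` scales with
#' sqrt(n) and with the device amplitude scale, so the published default
#' cutoff of 2.1 presumes device-native units.
#'
#' @param d_e Euclidean limb distance (finite, >= 0).
#' @param threshold positive decision cutoff; default 2.1.
#' @return `TRUE` for AF, `FALSE` otherwise.
#' @export
detect_af <- function(d_e, threshold = 2.1) {
  if (!is.finite(d_e)) stop("d_e must be finite")
  d_e > threshold
}

#' Measure pulse rate variability and detect AF on one recording
#'
#' The full pipeline: derivative-threshold segmentation with automatic
#' threshold selection, quality screening, 50% two-sided expansion,
#' fiducial-aligned averaging, limb extraction and the three distance
#' indexes, ending in the AF decision on `d_e`.
#'
#' @param series a [pulse_series()].
#' @param config a [prv_config()].
#' @return a `prv_result`: `d_e`, `d_m`, `d_c`, `n` (limb length),
#'   `n_averaged`, `fs`, `threshold_used`, `is_af`, `segmentation_threshold`,
#'   plus the `averaged` waveform for inspection.
#' @export
#' @examples
#' sr <- simulate_rhythm("SR", n_beats = 20, fs = 250, seed = 7)
#' measure_prv(sr)
measure_prv <- function(series, config = prv_config()) {
  stopifnot(inherits(series, "pulse_series"), inherits(config, "prv_config"))
  if (config$normalize) {
    iqr <- diff(quantile(series$samples, c(0.25, 0.75), names = FALSE))
    if (iqr > 0) series$samples <- series$samples / iqr
  }
  if (!is.null(config$resample_fs) && config$resample_fs != series$fs) {
    n_out <- max(2L, as.integer(round(length(series$samples) / series$fs *
                                        config$resample_fs)))
    series <- pulse_series(
      approx(seq_along(series$samples), series$samples,
             xout = seq(1, length(series$samples), length.out = n_out))$y,
      fs = config$resample_fs, id = series$id, label = series$label)
  }
  seg <- select_threshold(series, config)
  ex <- expand_segments(series, seg, fraction = config$expansion_fraction)
  if (length(ex) == 0L)
    stop("no expanded segments: recording too short for the expansion window")
  avg <- align_and_average(ex, fs = series$fs)
  pair <- extract_limbs(avg)
  d <- limb_distances(pair)
  structure(
    list(id = series$id, d_e = d$d_e, d_m = d$d_m, d_c = d$d_c, n = d$n,
         n_averaged = avg$n_averaged, fs = series$fs,
         threshold_used = config$af_threshold,
         is_af = detect_af(d$d_e, config$af_threshold),
         segmentation_threshold = seg$threshold,
         averaged = avg),
    class = "prv_result")
}

#' @export
print.prv_result <- function(x, ...) {
  cat(sprintf(
    "<prv_result '%s'>\n  d_e = %.4f  d_m = %.4f  d_c = %.5f  (n = %d)\n  N averaged = %d, fs = %g Hz, segmentation threshold %.1f\n  decision: %s (d_e %s %.2f)\n",
    x$id, x$d_e, x$d_m, x$d_c, x$n, x$n_averaged, x$fs,
    x$segmentation_threshold,
    if (x$is_af) "AF" else "non-AF",
    if (x$is_af) ">" else "<=", x$threshold_used))
  invisible(x)
}
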