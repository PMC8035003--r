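#' First derivative of a pulse series
#'
#' Forward first difference scaled by the sampling rate (amplitude/s),
#' aligned to the left sample: element `i` is the slope between samples `i`
#' and `i + 1`, so the result is one sample shorter than the input.  The
#' steep systolic upstroke produces one dominant derivative spike per beat,
#' essentially immune to baseline wander, which is what the segmentation
#' thresholds on.
#'
#' @param series a [pulse_series()].
#' @param smooth odd integer width of a centred moving average applied to
#'   the difference sequence; 1 means no smoothing.
#' @return numeric vector of length `length(series) - 1`.
#' @export
pulse_derivative <- function(series, smooth = 1L) {
  stopifnot(inherits(series, "pulse_series"))
  d <- diff(series$samples) * series$fs
  smooth <- as.integer(smooth)
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    pad <- (smooth - 1L) %/% 2L
    d <- as.numeric(stats::filter(c(rep(d[1L], pad), d, rep(d[length(d)], pad)),
                                  k, sides = 2L))
    d <- d[(pad + 1L):(length(d) - pad)]
  }
  d
}

new_segmentation <- function(threshold, cut_points, segments, n_normal = NA_integer_) {
  structure(list(threshold = threshold, cut_points = cut_points,
                 segments = segments, n_normal = n_normal),
            class = "prv_segmentation")
}

#' @export
print.prv_segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> threshold %.2f: %d cut points, %d segments (%s normal)\n",
              x$threshold, length(x$cut_points), nrow(x$segments),
              ifelse(is.na(x$n_normal), "?", x$n_normal)))
  invisible(x)
}

#' Segment a pulse series at one derivative threshold
#'
#' Beat onsets are located on the normalized derivative: wherever it crosses
#' `threshold` (a fraction of the global derivative maximum) upward, the
#' nearest preceding point where the derivative turns from non-positive to
#' positive — the foot of the systolic upstroke — becomes a cut point.
#' Crossings with no such zero point within one median inter-crossing
#' interval are discarded, and duplicate cut points collapse to one.
#' Segments are the half-open sample intervals `[start, end)` between
#' consecutive cut points.
#'
#' @param series a [pulse_series()].
#' @param threshold fraction of the global derivative maximum, in (0, 1).
#' @param deriv optional precomputed [pulse_derivative()] (a cache for
#'   callers that try several thresholds).
#' @return a `prv_segmentation`: `threshold`, integer `cut_points`, and a
#'   data frame `segments` with 1-based half-open columns `start`, `end`.
#'   Fewer than 2 usable cut points yield an empty segment table, not an
#'   error.
#' @export
segment_at_threshold <- function(series, threshold, deriv = NULL) {
  stopifnot(inherits(series, "pulse_series"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  d <- if (is.null(deriv)) pulse_derivative(series) else deriv
  dmax <- max(d)
  empty <- new_segmentation(threshold, integer(0),
                            data.frame(start = integer(0), end = integer(0)))
  if (!(dmax > 0)) return(empty)
  dn <- d / dmax

  # upward crossings of the threshold on the normalized derivative
  cross <- which(dn[-1L] >= threshold & dn[-length(dn)] < threshold) + 1L
  if (length(cross) == 0L) return(empty)

  # nearest preceding index where the derivative is <= 0 (followed by > 0);
  # the signal foot is the sample right after that index
  nonpos <- which(d <= 0)
  prec <- if (length(nonpos)) nonpos[findInterval(cross - 1L, nonpos)] else
    rep(NA_integer_, length(cross))
  prec[findInterval(cross - 1L, nonpos) == 0L] <- NA_integer_

  med_gap <- if (length(cross) > 1L) median(diff(cross)) else Inf
  ok <- !is.na(prec) & (cross - prec) <= med_gap
  cuts <- sort(unique(prec[ok] + 1L))
  if (length(cuts) < 2L)
    return(new_segmentation(threshold, cuts,
                            data.frame(start = integer(0), end = integer(0))))
  segs <- data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
  new_segmentation(threshold, cuts, segs)
}

#' Segment quality screen
#'
#' Labels one segment `"normal"` or `"abnormal"`.  The default `"rules"`
#' strategy is a rule-based stand-in for a trained per-beat quality
#' classifier, requiring that a segment look like a single pulse period:
#' \itemize{
#'   \item cycle duration within 0.3-2.0 s (20-200 bpm), and -- when a
#'     cohort `context` is available -- at least 70% of the cohort's 75th
#'     percentile segment duration, so that fragments of a cycle split at
#'     the dicrotic wave do not pass as whole periods;
#'   \item amplitude range within 0.3-3 times the cohort median segment
#'     range (when a cohort `context` is available);
#'   \item segment boundaries in the lowest 20% of the segment's amplitude
#'     range: a true period runs diastolic foot to diastolic foot;
#'   \item max-to-median absolute-slope ratio at most `context$max_deriv_ratio`
#'     (default 50) — rejects isolated spikes;
#'   \item coherent slope direction: among slopes above 10% of the segment
#'     maximum, at most 40% sign flips — a pulse rises and falls in long
#'     runs, noise flips incoherently;
#'   \item at least 55% of samples below the segment midrange — pulse
#'     periods spend most of the cycle in low-amplitude diastole, unlike
#'     noise.
#' }
#' `"none"` accepts everything.  A function strategy receives
#' `(samples, fs, context)` and returns `TRUE` for normal.
#'
#' @param samples numeric vector, one segment of the recording.
#' @param fs sampling rate in Hz.
#' @param strategy `"rules"`, `"none"`, or a function.
#' @param context optional named list of cohort statistics
#'   (`median_range`, `max_deriv_ratio`).
#' @return `"normal"` or `"abnormal"`.
#' @export
assess_quality <- function(samples, fs, strategy = "rules", context = NULL) {
  if (length(samples) == 0L) stop("empty segment")
  if (is.function(strategy))
    return(if (isTRUE(strategy(samples, fs, context))) "normal" else "abnormal")
  if (identical(strategy, "none")) return("normal")
  if (!identical(strategy, "rules"))
    stop("unknown quality strategy: ", strategy)

  dur <- length(samples) / fs
  if (dur < 0.3 || dur > 2.0) return("abnormal")
  if (!is.null(context$duration_p75) && is.finite(context$duration_p75) &&
      dur < 0.7 * context$duration_p75) return("abnormal")

  rng <- diff(range(samples))
  if (!is.null(context$median_range) && is.finite(context$median_range) &&
      context$median_range > 0) {
    if (rng < 0.3 * context$median_range || rng > 3 * context$median_range)
      return("abnormal")
  }
  if (rng > 0) {
    lo <- min(samples) + 0.2 * rng
    if (samples[1L] > lo || samples[length(samples)] > lo) return("abnormal")
  }

  dd <- diff(samples)
  ad <- abs(dd)
  mad_ <- median(ad)
  ratio_max <- if (is.null(context$max_deriv_ratio)) 50 else context$max_deriv_ratio
  if (mad_ > 0 && max(ad) / mad_ > ratio_max) return("abnormal")

  # slope coherence: the significant slopes of a pulse period come in long
  # same-sign runs (upstroke, downstroke); incoherent flipping is noise
  keep <- ad > 0.1 * max(ad)
  s <- sign(dd[keep])
  if (length(s) > 4L && mean(s[-1L] != s[-length(s)]) > 0.4) return("abnormal")

  if (rng > 0) {
    mid <- min(samples) + rng / 2
    if (mean(samples < mid) < 0.55) return("abnormal")
  }
  "normal"
}

quality_context <- function(series, seg) {
  rngs <- vapply(seq_len(nrow(seg$segments)), function(k) {
    s <- seg$segments$start[k]; e <- seg$segments$end[k]
    diff(range(series$samples[s:(e - 1L)]))
  }, 0.0)
  durs <- (seg$segments$end - seg$segments$start) / series$fs
  list(median_range = if (length(rngs)) median(rngs) else NA_real_,
       duration_p75 = if (length(durs)) quantile(durs, 0.75, names = FALSE)
                      else NA_real_,
       max_deriv_ratio = 50)
}

apply_quality <- function(series, seg, strategy) {
  if (nrow(seg$segments) == 0L) {
    seg$segments$normal <- logical(0)
    seg$n_normal <- 0L
    return(seg)
  }
  ctx <- quality_context(series, seg)
  lab <- vapply(seq_len(nrow(seg$segments)), function(k) {
    s <- seg$segments$start[k]; e <- seg$segments$end[k]
    assess_quality(series$samples[s:(e - 1L)], series$fs, strategy, ctx)
  }, "")
  seg$segments$normal <- lab == "normal"
  seg$n_normal <- sum(seg$segments$normal)
  seg
}

#' Select the best segmentation threshold
#'
#' Runs [segment_at_threshold()] followed by the quality screen for every
#' trial threshold in the configuration and returns the segmentation with
#' the maximum number of normal segments.  Ties are broken toward the
#' smallest threshold, making the choice deterministic.
#'
#' @param series a [pulse_series()].
#' @param config a [prv_config()].
#' @return the winning `prv_segmentation`, with per-segment `normal` flags
#'   and `n_normal` filled in.
#' @export
select_threshold <- function(series, config = prv_config()) {
  stopifnot(inherits(series, "pulse_series"), inherits(config, "prv_config"))
  d <- pulse_derivative(series, smooth = config$smooth_derivative)
  best <- NULL
  for (thr in config$trial_thresholds) {
    seg <- segment_at_threshold(series, thr, deriv = d)
    seg <- apply_quality(series, seg, config$quality_model)
    if (is.null(best) || seg$n_normal > best$n_normal) best <- seg
  }
  if (best$n_normal == 0L)
    stop("unusable signal: no trial threshold yields any normal segment")
  best
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expand normal segments on both sides
#'
#' Each quality-passing segment `[s, e)` of length `L` is widened by
#' `round(fraction * L)` samples on each side so that, at the default
#' fraction 0.5, the window covers the period itself plus half of each
#' neighbouring period — two adjacent periods in total around the fiducial.
#' Windows that would extend beyond the recording are dropped.  The fiducial
#' is the maximum of the derivative within the core (unexpanded) period,
#' stored relative to the window start.
#'
#' @param series a [pulse_series()].
#' @param seg a quality-screened `prv_segmentation` (from
#'   [select_threshold()]); segments without `normal` flags are all used.
#' @param fraction expansion fraction, >= 0 (0 reproduces the bare periods).
#' @return list of `expanded_segment` objects, each with `samples`,
#'   `fiducial` (1-based index into `samples`), `core` (1-based half-open
#'   `(start, end)` of the original period within the window) and
#'   `source_period`.
#' @export
expand_segments <- function(series, seg, fraction = 0.5) {
  stopifnot(inherits(series, "pulse_series"), inherits(seg, "prv_segmentation"))
  if (fraction < 0) stop("fraction must be >= 0")
  x <- series$samples
  d <- diff(x)                       # unscaled slope: same argmax as derivative
  n <- length(x)
  keep <- if ("normal" %in% names(seg$segments)) which(seg$segments$normal)
          else seq_len(nrow(seg$segments))
  out <- vector("list", length(keep))
  used <- 0L
  for (k in keep) {
    s <- seg$segments$start[k]; e <- seg$segments$end[k]
    L <- e - s
    m <- as.integer(round_half_away(fraction * L))
    ws <- s - m; we <- e + m
    if (ws < 1L || we > n + 1L) next    # window leaves the recording
    j_hi <- min(e - 2L, length(d))
    if (j_hi < s) next                  # degenerate 1-sample core
    fid_abs <- s - 1L + which.max(d[s:j_hi])
    used <- used + 1L
    out[[used]] <- structure(
      list(samples = x[ws:(we - 1L)],
           fiducial = fid_abs - ws + 1L,
           core = c(start = s - ws + 1L, end = e - ws + 1L),
           source_period = k),
      class = "expanded_segment")
  }
  out[seq_len(used)]
}
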