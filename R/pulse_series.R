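#' Construct a pulse series
#'
#' A `pulse_series` is a uniformly sampled single-channel pulse wave:
#' a numeric amplitude vector (device units) plus its sampling rate.
#'
#' @param samples numeric vector of amplitudes; at least 2 finite values.
#' @param fs sampling rate in Hz (> 0).
#' @param id free-text record identifier.
#' @param label optional rhythm annotation: one of `"AF"`, `"PC"`, `"SR"`,
#'   or `NA` for unknown.
#' @return an object of class `pulse_series` with fields `samples`, `fs`,
#'   `id`, `label`.
#' @seealso [read_pulse_series()], [measure_prv()]
#' @export
#' @examples
#' ps <- pulse_series(sin(seq(0, 4 * pi, length.out = 200)), fs = 100)
#' ps
pulse_series <- function(samples, fs, id = "series", label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a pulse series needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("pulse series samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  label <- as.character(label)
  if (!is.na(label) && !label %in% c("AF", "PC", "SR"))
    stop("label must be one of 'AF', 'PC', 'SR' or NA")
  structure(
    list(samples = samples, fs = as.numeric(fs), id = as.character(id),
         label = label),
    class = "pulse_series"
  )
}

#' @export
print.pulse_series <- function(x, ...) {
  cat(sprintf("<pulse_series '%s'> %d samples @ %g Hz (%.2f s)%s\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' @export
length.pulse_series <- function(x) length(x$samples)

#' Read a pulse series from a text file
#'
#' The canonical on-disk format is a single-column CSV of amplitude samples,
#' optionally preceded by a header line `fs=<Hz>`.  A two-column
#' `time,amplitude` CSV is also accepted (fs inferred from the time column
#' unless given).  Comment lines starting with `#` are ignored.
#'
#' @param path path to an existing file.
#' @param fs sampling rate in Hz; overrides any rate found in the file.
#'   Required when the file itself carries none.
#' @param id record identifier; defaults to the file name.
#' @param label optional rhythm annotation.
#' @return a [pulse_series()].
#' @export
read_pulse_series <- function(path, fs = NULL, id = NULL, label = NA_character_) {
  if (!file.exists(path) || dir.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty pulse series file: ", path)

  file_fs <- NULL
  hdr <- grepl("^\\s*fs\\s*[=:]", lines[1L])
  if (hdr) {
    file_fs <- suppressWarnings(as.numeric(sub("^\\s*fs\\s*[=:]\\s*", "", lines[1L])))
    if (is.na(file_fs))
      stop("unparseable fs header on line ", lineno[1L], " of ", path)
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) == 0L)
    stop("no samples in ", path)

  fields <- strsplit(lines, ",", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol > 2L))
    stop("more than 2 columns on line ", lineno[which(ncol > 2L)[1L]], " of ", path)
  two_col <- all(ncol == 2L)
  vals <- suppressWarnings(as.numeric(vapply(fields, function(f) f[[length(f)]], "")))
  if (anyNA(vals))
    stop("non-numeric value on line ", lineno[which(is.na(vals))[1L]], " of ", path)
  if (two_col && is.null(fs) && is.null(file_fs)) {
    tt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
    if (anyNA(tt))
      stop("non-numeric time value on line ", lineno[which(is.na(tt))[1L]], " of ", path)
    dt <- diff(tt)
    if (length(dt) < 1L || any(dt <= 0))
      stop("time column is not strictly increasing in ", path)
    file_fs <- 1 / median(dt)
  }

  use_fs <- if (!is.null(fs)) fs else file_fs
  if (is.null(use_fs))
    stop("sampling rate unknown: supply fs= header in the file or the fs argument")
  pulse_series(vals, fs = use_fs,
               id = if (is.null(id)) basename(path) else id, label = label)
}

#' Write a pulse series to the canonical CSV format
#'
#' Writes an `fs=<Hz>` header line followed by one amplitude per line, with
#' full double precision so that [read_pulse_series()] round-trips exactly.
#'
#' @param series a [pulse_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pulse_series <- function(series, path) {
  stopifnot(inherits(series, "pulse_series"))
  writeLines(c(sprintf("fs=%.17g", series$fs),
               sprintf("%.17g", series$samples)), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the detection pipeline.  Defaults are
#' the published operating values: trial segmentation thresholds 0.1-0.9 in
#' steps of 0.1, AF decision threshold 2.1 on the Euclidean limb distance
#' (raw amplitude-distance units), and 50% expansion of each period on both
#' sides.
#'
#' @param trial_thresholds strictly increasing values in (0, 1): fractions of
#'   the global derivative maximum tried during segmentation.
#' @param af_threshold positive decision cutoff on the Euclidean limb
#'   distance; `d_e > af_threshold` is called AF.
#' @param expansion_fraction nonnegative fraction by which each normal
#'   segment is expanded on both sides before averaging (0.5 covers two
#'   adjacent periods).
#' @param quality_model segment quality strategy: `"rules"` (default
#'   rule-based screen), `"none"` (accept everything), or a function
#'   `f(samples, fs, context)` returning `TRUE` for normal.
#' @param resample_fs optional target sampling rate; `NULL` leaves the
#'   signal at its native rate.
#' @param normalize if `TRUE`, amplitudes are rescaled to unit interquartile
#'   range before processing.  Off by default: the published 2.1 cutoff is
#'   in device-native amplitude units.
#' @param smooth_derivative odd integer width of a moving-average smoother
#'   applied to the derivative before thresholding; 1 (default) means the
#'   plain first difference.
#' @return an object of class `prv_config`.
#' @export
prv_config <- function(trial_thresholds = seq(0.1, 0.9, by = 0.1),
                       af_threshold = 2.1,
                       expansion_fraction = 0.5,
                       quality_model = "rules",
                       resample_fs = NULL,
                       normalize = FALSE,
                       smooth_derivative = 1L) {
  trial_thresholds <- as.numeric(trial_thresholds)
  if (length(trial_thresholds) == 0L ||
      any(trial_thresholds <= 0) || any(trial_thresholds >= 1) ||
      is.unsorted(trial_thresholds, strictly = TRUE))
    stop("trial_thresholds must be strictly increasing values in (0, 1)")
  if (!is.numeric(af_threshold) || af_threshold <= 0)
    stop("af_threshold must be > 0")
  if (!is.numeric(expansion_fraction) || expansion_fraction < 0)
    stop("expansion_fraction must be >= 0")
  if (!is.function(quality_model) &&
      !(is.character(quality_model) && quality_model %in% c("rules", "none")))
    stop("unknown quality model: ", quality_model)
  sw <- as.integer(smooth_derivative)
  if (sw < 1L || sw %% 2L == 0L)
    stop("smooth_derivative must be an odd positive integer")
  structure(
    list(trial_thresholds = trial_thresholds,
         af_threshold = as.numeric(af_threshold),
         expansion_fraction = as.numeric(expansion_fraction),
         quality_model = quality_model,
         resample_fs = resample_fs,
         normalize = isTRUE(normalize),
         smooth_derivative = sw),
    class = "prv_config"
  )
}

#' Write / read a detection report
#'
#' Serializes a [measure_prv()] result to JSON.  All numeric fields
#' round-trip losslessly (`digits = NA`).
#'
#' @param result a `prv_result` (see [measure_prv()]) or a named list with at
#'   least `d_e`, `d_m`, `d_c`, `n_averaged`, `threshold_used`, `is_af`.
#' @param path output file path; must not be a directory.
#' @return `path` invisibly (write); a named list (read).
#' @export
write_report <- function(result, path) {
  need <- c("d_e", "d_m", "d_c", "n_averaged", "threshold_used", "is_af")
  miss <- setdiff(need, names(result))
  if (length(miss))
    stop("result is missing fields: ", paste(miss, collapse = ", "))
  if (dir.exists(path))
    stop("path is a directory: ", path)
  out <- result[!vapply(result, is.object, TRUE)]
  out$decision <- if (isTRUE(result$is_af)) "AF" else "non-AF"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
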