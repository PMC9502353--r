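#' Uniformly sampled physiological signal
#'
#' Container for a single-channel waveform (PPG, ECG, or an ACC-derived
#' envelope) sampled on a regular grid. The time of sample `k` (1-based) is
#' `t0 + (k - 1) / fs`.
#'
#' @param values Numeric vector of amplitudes (arbitrary units). Must be
#'   finite and of length >= 1.
#' @param fs Sampling rate in Hz, > 0.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `uniform_signal` with fields `values`, `fs`,
#'   `t0`.
#' @export
uniform_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(values))) stop("signal values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(values = values, fs = fs, t0 = as.numeric(t0)),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("uniform_signal: %d samples @ %g Hz, t0 = %g s (%.1f s)\n",
              length(x$values), x$fs, x$t0, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample times of a uniform signal
#' @param signal A `uniform_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(signal) {
  signal$t0 + (seq_along(signal$values) - 1) / signal$fs
}

#' Triaxial accelerometer signal
#'
#' @param x,y,z Equal-length numeric vectors of acceleration (device units).
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return An object of class `triaxial_signal`.
#' @export
triaxial_signal <- function(x, y, z, fs, t0 = 0) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(x) != length(y) || length(y) != length(z))
    stop("the three axes must have equal length")
  if (fs <= 0) stop("fs must be positive")
  structure(list(x = x, y = y, z = z, fs = fs, t0 = as.numeric(t0)),
            class = "triaxial_signal")
}

#' Beat train: detected event times
#'
#' Strictly increasing times (s) of detected R-peaks or systolic peaks.
#'
#' @param times Numeric vector of event times in seconds.
#' @return An object of class `beat_train`.
#' @export
beat_train <- function(times) {
  times <- as.numeric(times)
  if (length(times) && (!all(is.finite(times)) || any(times < 0)))
    stop("beat times must be finite and non-negative")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("beat times must be strictly increasing")
  structure(list(times = times), class = "beat_train")
}

#' @export
print.beat_train <- function(x, ...) {
  cat(sprintf("beat_train: %d beats", length(x$times)))
  if (length(x$times) > 1L)
    cat(sprintf(", span %.2f-%.2f s, mean interval %.3f s",
                x$times[1], x$times[length(x$times)],
                mean(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' Unevenly time-stamped inter-beat interval series
#'
#' `anchor_times[k]` is the time of the beat ending interval `k`;
#' `durations[k]` is its length in seconds.
#'
#' @param anchor_times Strictly increasing times in seconds.
#' @param durations Positive interval durations in seconds.
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(anchor_times, durations) {
  anchor_times <- as.numeric(anchor_times)
  durations <- as.numeric(durations)
  if (length(anchor_times) != length(durations))
    stop("anchor_times and durations must have equal length")
  if (any(durations <= 0)) stop("durations must be positive")
  if (length(anchor_times) > 1L && any(diff(anchor_times) <= 0))
    stop("anchor_times must be strictly increasing")
  structure(list(anchor_times = anchor_times, durations = durations),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("interval_series: %d intervals, mean %.3f s\n",
              length(x$durations),
              if (length(x$durations)) mean(x$durations) else NA_real_))
  invisible(x)
}

#' Evenly resampled variability series
#'
#' Interval durations (s) sampled on a uniform grid; the unit of metric
#' comparison and spectral estimation.
#'
#' @param values Interval durations in seconds on the uniform grid.
#' @param fs_v Grid rate in Hz (10 Hz intermediate or 1 Hz final).
#' @param t0 Time of the first grid point in seconds.
#' @return An object of class `uniform_variability`.
#' @export
uniform_variability <- function(values, fs_v, t0 = 0) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("variability values must be finite")
  if (fs_v <= 0) stop("fs_v must be positive")
  structure(list(values = values, fs_v = fs_v, t0 = as.numeric(t0)),
            class = "uniform_variability")
}

#' @export
print.uniform_variability <- function(x, ...) {
  cat(sprintf("uniform_variability: %d samples @ %g Hz, mean %.3f s\n",
              length(x$values), x$fs_v, mean(x$values)))
  invisible(x)
}

# Read a delimited table, tolerating an optional single header line
# (detected by a non-numeric first row). Comma-separated.
read_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  has_header <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1]])))
  tab <- utils::read.csv(path, header = has_header,
                         colClasses = "character",
                         blank.lines.skip = TRUE)
  num <- as.data.frame(lapply(tab, function(col) {
    suppressWarnings(as.numeric(col))
  }))
  bad <- which(!stats::complete.cases(num))
  if (length(bad))
    stop(sprintf("non-numeric row %d in %s", bad[1] + has_header, path))
  num
}

#' Read a uniformly sampled signal from delimited text
#'
#' Accepts one-column (`value`) or two-column (`time,value`) comma-separated
#' text with an optional header line. When a time column is present its
#' spacing is checked against `1/fs` (maximum deviation < 10% of the sample
#' period) and its first entry becomes `t0`.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz. May be `NULL` for two-column files, in
#'   which case it is derived from the median time spacing.
#' @param time_unit `"s"` (default) or `"ms"`; device timestamps in
#'   milliseconds are converted to seconds at read time.
#' @return A [uniform_signal()].
#' @export
read_signal <- function(path, fs = NULL, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  tab <- read_numeric_table(path)
  if (ncol(tab) == 1L) {
    if (is.null(fs)) stop("fs is required for a one-column file")
    return(uniform_signal(tab[[1]], fs = fs, t0 = 0))
  }
  tt <- tab[[1]]
  if (time_unit == "ms") tt <- tt / 1000
  vv <- tab[[2]]
  if (length(tt) > 1L) {
    dt <- diff(tt)
    if (is.null(fs)) fs <- 1 / stats::median(dt)
    dev <- abs(dt - 1 / fs) * fs
    if (any(dev >= 0.10)) {
      k <- which(dev >= 0.10)[1]
      stop(sprintf(
        "non-uniform time column in %s: spacing %.6g s at row %d deviates >= 10%% from 1/fs = %.6g s",
        path, dt[k], k + 1L, 1 / fs))
    }
  } else if (is.null(fs)) {
    stop("fs is required for a single-row file")
  }
  uniform_signal(vv, fs = fs, t0 = tt[1])
}

#' Write a uniform signal as `time,value` CSV
#'
#' @param signal A [uniform_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "uniform_signal"))
  df <- data.frame(time = signal_times(signal), value = signal$values)
  ok <- tryCatch({
    utils::write.table(format(df, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE,
                       col.names = c("time", "value"), quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a beat train (single `time` column, seconds)
#' @param path Path to the file.
#' @return A [beat_train()].
#' @export
read_beats <- function(path) {
  tab <- read_numeric_table(path)
  beat_train(tab[[1]])
}

#' Write a beat train as a one-column CSV
#' @param beats A [beat_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_train"))
  utils::write.table(data.frame(time = beats$times), path, sep = ",",
                     row.names = FALSE, col.names = "time", quote = FALSE)
  invisible(path)
}

#' Read an interval series (`anchor_time,duration` CSV)
#' @param path Path to the file.
#' @return An [interval_series()].
#' @export
read_intervals <- function(path) {
  tab <- read_numeric_table(path)
  if (ncol(tab) < 2L) stop("interval file needs anchor_time,duration columns")
  interval_series(tab[[1]], tab[[2]])
}

#' Write an interval series as `anchor_time,duration` CSV
#' @param iv An [interval_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path) {
  stopifnot(inherits(iv, "interval_series"))
  utils::write.table(data.frame(anchor_time = iv$anchor_times,
                                duration = iv$durations),
                     path, sep = ",", row.names = FALSE,
                     col.names = c("anchor_time", "duration"), quote = FALSE)
  invisible(path)
}

#' Cubic-spline resampling of a uniform signal
#'
#' Interpolates with a cubic spline and re-evaluates on a new uniform grid
#' spanning the same time range. The interpolant passes through all original
#' samples, so upsampling followed by evaluation at the original instants
#' reproduces the input.
#'
#' @param signal A [uniform_signal()], length >= 4.
#' @param target_fs New sampling rate in Hz (default 1000).
#' @return A [uniform_signal()] at `target_fs`.
#' @export
resample_cubic <- function(signal, target_fs = 1000) {
  stopifnot(inherits(signal, "uniform_signal"))
  if (length(signal$values) < 4L)
    stop("cubic resampling needs at least 4 samples")
  if (target_fs <= 0) stop("target_fs must be positive")
  tt <- signal_times(signal)
  f <- stats::splinefun(tt, signal$values, method = "fmm")
  span <- tt[length(tt)] - tt[1]
  n_out <- floor(span * target_fs) + 1L
  t_out <- tt[1] + (seq_len(n_out) - 1) / target_fs
  uniform_signal(f(t_out), fs = target_fs, t0 = tt[1])
}
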