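#' Tap envelope of a triaxial accelerometer trace
#'
#' Locates synchronization taps: the squared three-axis signals are summed,
#' the arithmetic mean subtracted, the result smoothed with a centered
#' moving average, the analytic (Hilbert) envelope taken, and the envelope
#' min-max normalized to `[0, 1]`. Typical smoothing windows are 20 samples
#' for a 50 Hz smartwatch ACC, 34 for a 200 Hz chest-strap ACC and 16 for a
#' 64 Hz wristband ACC.
#'
#' @param acc A [triaxial_signal()].
#' @param smooth_window Moving-average window in samples (>= 1).
#' @return A [uniform_signal()] in `[0, 1]`.
#' @export
tap_envelope <- function(acc, smooth_window = 20) {
  stopifnot(inherits(acc, "triaxial_signal"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L) stop("smooth_window must be >= 1")
  energy <- acc$x ^ 2 + acc$y ^ 2 + acc$z ^ 2
  energy <- energy - mean(energy)
  sm <- rolling_window_stats(energy,
                             smooth_window + (1 - smooth_window %% 2L))$mean
  env <- analytic_envelope(sm)
  rng <- range(env)
  if (rng[2] - rng[1] <= 1e-15 * max(abs(rng), 1))
    stop("accelerometer energy is constant; tap envelope undefined")
  uniform_signal((env - rng[1]) / (rng[2] - rng[1]),
                 fs = acc$fs, t0 = acc$t0)
}

#' Report the K largest well-separated envelope peaks
#'
#' Helper replacing manual timestamp picking: candidate tap instants for the
#' user to confirm.
#'
#' @param envelope A [tap_envelope()] output.
#' @param k Number of peaks to report.
#' @param min_separation Minimum separation between reported peaks in s.
#' @return Numeric vector of peak times, ordered by amplitude.
#' @export
report_tap_peaks <- function(envelope, k = 2, min_separation = 1) {
  stopifnot(inherits(envelope, "uniform_signal"))
  x <- envelope$values
  cand <- local_maxima(x)
  if (!length(cand)) return(numeric(0))
  gap <- round(min_separation * envelope$fs)
  cand <- enforce_separation(cand, x[cand], gap)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  envelope$t0 + (utils::head(cand, k) - 1L) / envelope$fs
}

#' Shift a signal in time
#'
#' Applies an externally determined synchronization offset: `t0` moves by
#' `offset`, values are untouched.
#'
#' @param signal A [uniform_signal()].
#' @param offset Offset in seconds.
#' @return The shifted [uniform_signal()].
#' @export
apply_offset <- function(signal, offset) {
  stopifnot(inherits(signal, "uniform_signal"))
  uniform_signal(signal$values, fs = signal$fs, t0 = signal$t0 + offset)
}
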