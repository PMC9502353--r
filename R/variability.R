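#' Physiological screening bounds for inter-beat intervals
#'
#' Defaults correspond to the physiological heart-rate range 40-200 bpm:
#' intervals of 0.3-1.5 s.
#'
#' @param lo Lower bound in seconds (default 0.3).
#' @param hi Upper bound in seconds (default 1.5).
#' @return A list of class `screening_bounds`.
#' @export
screening_bounds <- function(lo = 0.3, hi = 1.5) {
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  structure(list(lo = lo, hi = hi), class = "screening_bounds")
}

#' Autoregressive correction parameters
#'
#' @param window Sliding-window length in samples (default 25).
#' @param order AR model order (default 8), must be < `window`.
#' @param replace_k Replacement gate in innovation-SD multiples (default 1).
#' @return A list of class `ar_params`.
#' @export
ar_params <- function(window = 25, order = 8, replace_k = 1) {
  if (order >= window) stop("order must be smaller than window")
  if (replace_k <= 0) stop("replace_k must be positive")
  structure(list(window = as.integer(window), order = as.integer(order),
                 replace_k = replace_k), class = "ar_params")
}

#' Inter-beat intervals from a beat train
#'
#' `durations[k] = times[k+1] - times[k]`, anchored at the beat ending each
#' interval, so cumulative summation from the first beat reconstructs the
#' train.
#'
#' @param beats A [beat_train()] with at least two beats.
#' @return An [interval_series()].
#' @export
beats_to_intervals <- function(beats) {
  stopifnot(inherits(beats, "beat_train"))
  tt <- beats$times
  if (length(tt) < 2L) stop("need at least 2 beats to form intervals")
  interval_series(anchor_times = tt[-1L], durations = diff(tt))
}

#' Physiological interval screening
#'
#' One left-to-right pass over the durations. An interval shorter than
#' `bounds$lo` marks its ending beat as a false detection: it is removed and
#' its duration added to the following interval (to the preceding one when
#' it is the last). An interval longer than `bounds$hi` suggests a skipped
#' beat: it is split into two halves. Total summed duration is conserved.
#' Residual out-of-bounds intervals after the single pass are counted in the
#' `"events"` attribute rather than re-processed.
#'
#' @param iv An [interval_series()].
#' @param bounds A [screening_bounds()].
#' @return A screened [interval_series()] with an `"events"` attribute
#'   (`merged`, `split`, `residual` counts).
#' @export
screen_physiological <- function(iv, bounds = screening_bounds()) {
  stopifnot(inherits(iv, "interval_series"))
  dur <- iv$durations
  anc <- iv$anchor_times
  n <- length(dur)
  out_d <- numeric(0)
  out_a <- numeric(0)
  merged <- 0L
  split <- 0L
  k <- 1L
  while (k <= n) {
    d <- dur[k]
    a <- anc[k]
    if (d < bounds$lo) {
      merged <- merged + 1L
      if (k < n) {
        # ending beat was an artifact: fold into the following interval
        dur[k + 1L] <- dur[k + 1L] + d
      } else if (length(out_d)) {
        out_d[length(out_d)] <- out_d[length(out_d)] + d
        out_a[length(out_a)] <- a
      } else {
        out_d <- d
        out_a <- a
      }
      k <- k + 1L
      next
    }
    if (d > bounds$hi) {
      split <- split + 1L
      out_d <- c(out_d, d / 2, d / 2)
      out_a <- c(out_a, a - d / 2, a)
      k <- k + 1L
      next
    }
    out_d <- c(out_d, d)
    out_a <- c(out_a, a)
    k <- k + 1L
  }
  res <- interval_series(out_a, out_d)
  attr(res, "events") <- list(
    merged = merged, split = split,
    residual = sum(out_d < bounds$lo | out_d > bounds$hi))
  res
}

#' Local-statistics outlier correction
#'
#' Flags durations outside `mean +/- k * SD` of a centered moving window
#' (truncated at the edges; statistics computed once on the input). Flagged
#' long intervals are split in half; flagged short intervals are merged into
#' their successor (predecessor when last), mirroring the physiological
#' screening rules. Windows with zero spread treat every sample as inside
#' the band. Total summed duration is conserved.
#'
#' @param iv An [interval_series()].
#' @param window Moving-window length in samples (default 25).
#' @param k Band half-width in SD multiples (default 3).
#' @return A corrected [interval_series()] with an `"events"` attribute.
#' @export
correct_outliers_local <- function(iv, window = 25, k = 3) {
  stopifnot(inherits(iv, "interval_series"))
  window <- as.integer(window)
  if (window < 3L) stop("window must be >= 3")
  dur <- iv$durations
  anc <- iv$anchor_times
  n <- length(dur)
  st <- rolling_window_stats(dur, window + (1 - window %% 2L))
  hi_out <- st$sd > 0 & dur > st$mean + k * st$sd
  lo_out <- st$sd > 0 & dur < st$mean - k * st$sd
  out_d <- numeric(0)
  out_a <- numeric(0)
  merged <- 0L
  split <- 0L
  carry <- 0
  for (j in seq_len(n)) {
    d <- dur[j] + carry
    carry <- 0
    if (lo_out[j]) {
      merged <- merged + 1L
      if (j < n) {
        carry <- d
      } else if (length(out_d)) {
        out_d[length(out_d)] <- out_d[length(out_d)] + d
        out_a[length(out_a)] <- anc[j]
      } else {
        out_d <- d
        out_a <- anc[j]
      }
      next
    }
    if (hi_out[j]) {
      split <- split + 1L
      out_d <- c(out_d, d / 2, d / 2)
      out_a <- c(out_a, anc[j] - d / 2, anc[j])
      next
    }
    out_d <- c(out_d, d)
    out_a <- c(out_a, anc[j])
  }
  res <- interval_series(out_a, out_d)
  attr(res, "events") <- list(merged = merged, split = split)
  res
}

# Windowed-sinc low-pass with zero-phase application; order adapts to short
# series so signal::filtfilt stays well-posed.
zero_phase_lowpass <- function(x, fs, cutoff, order = 150L) {
  n <- length(x)
  ord <- min(order, 2L * ((n - 4L) %/% 6L))
  if (ord < 8L) return(x)                    # too short to filter meaningfully
  if (ord %% 2L == 1L) ord <- ord - 1L
  flt <- signal::fir1(ord, cutoff / (fs / 2), type = "low")
  flt <- signal::Ma(unclass(flt) / sum(flt))  # exact unit DC gain
  # pad with edge reflections to suppress filtfilt end transients
  pad <- min(n - 1L, ord)
  xe <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(flt, xe)
  y[(pad + 1L):(pad + n)]
}

#' Uniform resampling of an interval series
#'
#' Cubic-spline interpolation of (anchor time, duration) onto an
#' intermediate uniform grid, zero-phase low-pass filtering at the
#' physiological variability bound, and decimation to the output rate. The
#' output is limited to the anchor-time span (no extrapolation).
#'
#' @param iv An [interval_series()] with at least 4 intervals.
#' @param mid_fs Intermediate oversampling rate in Hz (default 10).
#' @param cutoff Low-pass cutoff in Hz (default 0.5).
#' @param out_fs Final rate in Hz (default 1); `mid_fs` must be an integer
#'   multiple.
#' @return A [uniform_variability()] at `out_fs`.
#' @export
to_uniform <- function(iv, mid_fs = 10, cutoff = 0.5, out_fs = 1) {
  stopifnot(inherits(iv, "interval_series"))
  n <- length(iv$durations)
  if (n < 4L) stop("need at least 4 intervals")
  span <- iv$anchor_times[n] - iv$anchor_times[1]
  if (span < 4 / out_fs) stop("anchor span too short for the output rate")
  dec <- mid_fs / out_fs
  if (abs(dec - round(dec)) > 1e-9)
    stop("mid_fs must be an integer multiple of out_fs")
  dec <- as.integer(round(dec))
  f <- stats::splinefun(iv$anchor_times, iv$durations, method = "fmm")
  t_mid <- seq(iv$anchor_times[1], iv$anchor_times[n], by = 1 / mid_fs)
  y_mid <- f(t_mid)
  y_f <- zero_phase_lowpass(y_mid, mid_fs, cutoff)
  keep <- seq(1L, length(y_f), by = dec)
  uniform_variability(y_f[keep], fs_v = out_fs, t0 = t_mid[1])
}

#' Autoregressive one-step correction of a variability series
#'
#' Slides a window of past samples along the series, fits an AR model
#' (Burg estimation on the mean-removed window), and predicts the next
#' sample together with its one-step forecast SD (the innovation SD inflated
#' for parameter-estimation uncertainty, `sqrt(var_pred (1 + p/w) w /
#' (w - p - 1))`). When the observed sample deviates from the prediction by
#' more than `replace_k` SD it is replaced by the prediction. Predictions are
#' always formed from the observed history, not from previously replaced
#' values: re-feeding replacements shrinks the apparent innovation variance
#' and cascades into wholesale smoothing. The first `window` samples pass
#' through unchanged. Constant windows (singular fits) skip the correction
#' step.
#'
#' @param series A [uniform_variability()] longer than `params$window`.
#' @param params An [ar_params()].
#' @return A corrected [uniform_variability()] with an `"events"` attribute
#'   (`replaced` indices, `skipped` count).
#' @export
ar_correct <- function(series, params = ar_params()) {
  stopifnot(inherits(series, "uniform_variability"))
  w <- params$window
  x <- series$values
  n <- length(x)
  if (n <= w) stop("series must be longer than the AR window")
  x0 <- series$values                 # observed history used for every fit
  replaced <- integer(0)
  skipped <- 0L
  for (i in (w + 1L):n) {
    win <- x0[(i - w):(i - 1L)]
    if (stats::sd(win) < 1e-12) {
      skipped <- skipped + 1L
      next
    }
    fit <- tryCatch(
      stats::ar.burg(win, order.max = params$order, aic = FALSE,
                     demean = TRUE),
      error = function(e) NULL)
    if (is.null(fit) || !length(fit$ar) || !is.finite(fit$var.pred)) {
      skipped <- skipped + 1L
      next
    }
    p <- length(fit$ar)
    pred <- fit$x.mean + sum(fit$ar * (win[w - seq_len(p) + 1L] - fit$x.mean))
    sd1 <- sqrt(max(fit$var.pred, 0) * (1 + p / w) * w / (w - p - 1))
    if (is.finite(sd1) && sd1 > 0 &&
        abs(x0[i] - pred) > params$replace_k * sd1) {
      x[i] <- pred
      replaced <- c(replaced, i)
    }
  }
  res <- uniform_variability(x, fs_v = series$fs_v, t0 = series$t0)
  attr(res, "events") <- list(replaced = replaced, skipped = skipped)
  res
}
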