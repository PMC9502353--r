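# Rolling sums over centered windows truncated at the edges, via cumsums.
rolling_window_stats <- function(x, window_len) {
  n <- length(x)
  h <- (window_len - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + h)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  nn <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  mean <- s / nn
  var <- pmax(0, (s2 - s * s / nn) / pmax(1L, nn - 1L))
  list(mean = mean, sd = sqrt(var), n = nn)
}

#' Adaptive standardization demodulation
#'
#' Divides each sample by the standard deviation of the signal over a
#' centered sliding window of odd length, equalizing amplitude across the
#' recording. Edge samples use truncated windows; windows with zero spread
#' fall back to an epsilon guard (1e-12 times the global SD) so the output
#' stays finite.
#'
#' @param signal A [uniform_signal()].
#' @param window_len Odd window length in samples, >= 3.
#' @return A [uniform_signal()]; attribute `"events"` counts guarded
#'   windows.
#' @export
adaptive_standardize <- function(signal, window_len = 125) {
  stopifnot(inherits(signal, "uniform_signal"))
  window_len <- as.integer(window_len)
  if (window_len < 3L || window_len %% 2L == 0L)
    stop("window_len must be odd and >= 3")
  if (window_len > length(signal$values))
    stop("window_len exceeds signal length")
  x <- signal$values
  st <- rolling_window_stats(x, window_len)
  gsd <- stats::sd(x)
  eps <- 1e-12 * if (gsd > 0) gsd else 1
  guarded <- st$sd < eps
  div <- ifelse(guarded, eps, st$sd)
  out <- uniform_signal(x / div, fs = signal$fs, t0 = signal$t0)
  attr(out, "events") <- list(zero_sd_windows = sum(guarded))
  out
}

#' Online extrema-based amplitude demodulation
#'
#' Sliding-window algorithm: within each centered window the mean is
#' removed, `Delta` = window max - window min is computed, interior local
#' maxima above `P * Delta` and local minima below `-P * Delta` are
#' collected, and the center sample is divided by the mean absolute value of
#' those qualifying extrema. Windows without qualifying extrema fall back to
#' `Delta / 2` as the divisor. The window slides by one sample; edge samples
#' use truncated windows.
#'
#' @param signal A [uniform_signal()].
#' @param window_len Odd window length in samples (default 5 s worth).
#' @param P Threshold fraction in (0, 1) gating the extrema (default 0.3).
#' @return A [uniform_signal()]; attribute `"events"` counts fallback
#'   windows.
#' @export
online_demodulate <- function(signal, window_len = NULL, P = 0.3) {
  stopifnot(inherits(signal, "uniform_signal"))
  if (is.null(window_len)) {
    window_len <- round(5 * signal$fs)
    if (window_len %% 2L == 0L) window_len <- window_len + 1L
  }
  window_len <- as.integer(window_len)
  if (window_len < 3L || window_len %% 2L == 0L)
    stop("window_len must be odd and >= 3")
  if (P <= 0 || P >= 1) stop("P must lie in (0, 1)")
  x <- signal$values
  n <- length(x)
  h <- (window_len - 1L) %/% 2L
  out <- numeric(n)
  fallbacks <- 0L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    w <- x[lo:hi] - mean(x[lo:hi])
    delta <- max(w) - min(w)
    if (delta <= 0) {
      out[i] <- 0
      next
    }
    m <- length(w)
    interior <- 2:(m - 1L)
    is_max <- w[interior] > w[interior - 1L] & w[interior] > w[interior + 1L]
    is_min <- w[interior] < w[interior - 1L] & w[interior] < w[interior + 1L]
    ext <- c(w[interior][is_max & w[interior] > P * delta],
             w[interior][is_min & w[interior] < -P * delta])
    if (length(ext)) {
      div <- mean(abs(ext))
    } else {
      div <- delta / 2
      fallbacks <- fallbacks + 1L
    }
    out[i] <- x[i] / div
  }
  res <- uniform_signal(out, fs = signal$fs, t0 = signal$t0)
  attr(res, "events") <- list(fallback_windows = fallbacks)
  res
}

#' Analytic envelope via the discrete Fourier transform
#'
#' Magnitude of the analytic extension (Hilbert-transform construction):
#' negative frequencies are zeroed, positive frequencies doubled.
#'
#' @param x Numeric vector.
#' @return Non-negative envelope vector of the same length.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1] <- 1
    w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * w, inverse = TRUE) / n)
}

#' Envelope (Hilbert) amplitude demodulation
#'
#' Divides the signal by the magnitude of its analytic extension, flattening
#' amplitude fluctuations to a near-unit envelope. Parameter-free; zero
#' crossings and their timing are preserved because the divisor is positive.
#'
#' @param signal A [uniform_signal()] with nonzero energy.
#' @return A [uniform_signal()]; attribute `"events"` counts
#'   epsilon-guarded samples.
#' @export
hilbert_demodulate <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  x <- signal$values
  rms <- sqrt(mean(x ^ 2))
  if (rms == 0) stop("signal has zero energy")
  env <- analytic_envelope(x)
  eps <- 1e-12 * rms
  guarded <- env < eps
  env[guarded] <- eps
  out <- uniform_signal(x / env, fs = signal$fs, t0 = signal$t0)
  attr(out, "events") <- list(guarded_samples = sum(guarded))
  out
}

#' Dispatch helper over the three demodulation methods
#'
#' @param signal A [uniform_signal()].
#' @param method `"hilbert"` (default), `"standardize"` or `"online"`.
#' @param window_len Window length for the windowed methods (odd samples;
#'   default 5 s worth).
#' @param P Threshold fraction for the online method.
#' @return A [uniform_signal()].
#' @export
demodulate <- function(signal, method = c("hilbert", "standardize", "online"),
                       window_len = NULL, P = 0.3) {
  method <- match.arg(method)
  if (is.null(window_len)) {
    window_len <- round(5 * signal$fs)
    if (window_len %% 2L == 0L) window_len <- window_len + 1L
  }
  switch(method,
         hilbert = hilbert_demodulate(signal),
         standardize = adaptive_standardize(signal, window_len),
         online = online_demodulate(signal, window_len, P))
}
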