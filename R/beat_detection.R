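# Enforce a refractory separation on candidate peaks: greedy by amplitude,
# so the larger peak wins a conflict.
enforce_separation <- function(idx, amp, min_gap_samples) {
  if (!length(idx)) return(integer(0))
  ord <- order(amp, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(idx[kept] - idx[i]) >= min_gap_samples))
      kept <- c(kept, i)
  }
  sort(idx[kept])
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

#' Pan-Tompkins R-peak detection
#'
#' Classic QRS detector operating on an already band-filtered ECG:
#' five-point derivative, squaring, 150 ms moving-window integration, dual
#' adaptive thresholds with search-back, 200 ms refractory period, and a
#' T-wave slope test for candidates within 360 ms of the previous beat.
#' Each accepted integrator fiducial is refined to the R-wave maximum of the
#' filtered ECG within +/- 50 ms.
#'
#' @param ecg A wavelet-filtered ECG [uniform_signal()], `fs >= 100` Hz.
#' @return A [beat_train()] of R-peak times.
#' @export
pan_tompkins <- function(ecg) {
  stopifnot(inherits(ecg, "uniform_signal"))
  fs <- ecg$fs
  if (fs < 100) stop("pan_tompkins requires fs >= 100 Hz")
  x <- ecg$values
  n <- length(x)
  if (n < 2 * fs) stop("signal shorter than 2 s; cannot initialize thresholds")

  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4])
  xp <- c(rep(x[1], 4L), x)
  der <- (2 * xp[5:(n + 4)] + xp[4:(n + 3)] - xp[2:(n + 1)] -
            2 * xp[1:n]) / 8
  sq <- der ^ 2
  w <- as.integer(max(1, round(0.150 * fs)))
  cs <- c(0, cumsum(sq))
  lo <- pmax(0L, seq_len(n) - w)
  mwi <- (cs[seq_len(n) + 1L] - cs[lo + 1L]) / w

  refractory <- round(0.2 * fs)
  twave_win <- round(0.36 * fs)

  peaks <- local_maxima(mwi)
  init <- mwi[seq_len(round(2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- function() npki + 0.25 * (spki - npki)

  accepted <- integer(0)
  acc_slope <- numeric(0)
  rr_hist <- numeric(0)
  slope_at <- function(i) {
    a <- max(1L, i - w); b <- min(n, i)
    max(abs(der[a:b]))
  }
  for (p in peaks) {
    pk <- mwi[p]
    if (length(accepted) && (p - accepted[length(accepted)]) < refractory)
      next
    is_beat <- FALSE
    if (pk > thr1()) {
      is_beat <- TRUE
      # T-wave discrimination: candidate close to the previous beat with a
      # shallower maximal slope is treated as a T wave
      if (length(accepted) &&
          (p - accepted[length(accepted)]) < twave_win &&
          slope_at(p) < 0.5 * acc_slope[length(acc_slope)])
        is_beat <- FALSE
    }
    if (is_beat) {
      spki <- 0.125 * pk + 0.875 * spki
      if (length(accepted)) {
        rr_hist <- c(rr_hist, p - accepted[length(accepted)])
        if (length(rr_hist) > 8L) rr_hist <- rr_hist[-1]
      }
      accepted <- c(accepted, p)
      acc_slope <- c(acc_slope, slope_at(p))
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back: if no beat for 1.66 mean RR, re-examine skipped peaks
      # against the lower threshold
      if (length(accepted) && length(rr_hist) &&
          (p - accepted[length(accepted)]) > 1.66 * mean(rr_hist)) {
        seg <- peaks[peaks > accepted[length(accepted)] + refractory &
                       peaks <= p]
        if (length(seg)) {
          cand <- seg[which.max(mwi[seg])]
          if (mwi[cand] > 0.5 * thr1()) {
            spki <- 0.25 * mwi[cand] + 0.75 * spki
            rr_hist <- c(rr_hist, cand - accepted[length(accepted)])
            if (length(rr_hist) > 8L) rr_hist <- rr_hist[-1]
            accepted <- sort(c(accepted, cand))
            acc_slope <- c(acc_slope, slope_at(cand))
          }
        }
      }
    }
  }
  if (!length(accepted)) return(beat_train(numeric(0)))

  # refine to the R maximum of the filtered ECG: the integrator peak sits on
  # a plateau anywhere up to one window length after the QRS, so search the
  # span the integration window covered, plus 50 ms of slack
  half <- as.integer(round(0.05 * fs))
  r_idx <- vapply(accepted, function(p) {
    a <- max(1L, as.integer(p) - w - half)
    b <- min(n, as.integer(p) + half)
    a + which.max(x[a:b]) - 1L
  }, integer(1))
  r_idx <- unique(r_idx)
  r_idx <- enforce_separation(r_idx, x[r_idx], refractory)
  beat_train(ecg$t0 + (r_idx - 1L) / fs)
}

#' Peak detection algorithm (PDA) for demodulated PPG
#'
#' Compares neighboring samples to find local maxima and accepts those whose
#' amplitude reaches `threshold` times the maximum of the surrounding 2 s of
#' signal. Peaks closer than 0.3 s are resolved in favor of the larger one.
#'
#' @param ppg A demodulated PPG [uniform_signal()] (near-unit envelope).
#' @param threshold Fraction of the rolling 2 s maximum (default 0.8).
#' @return A [beat_train()] of systolic-peak times.
#' @export
pda <- function(ppg, threshold = 0.8) {
  stopifnot(inherits(ppg, "uniform_signal"))
  x <- ppg$values
  n <- length(x)
  fs <- ppg$fs
  cand <- local_maxima(x)
  if (!length(cand)) return(beat_train(numeric(0)))
  half <- round(fs)                           # 2 s surrounding window
  keep <- vapply(cand, function(i) {
    a <- max(1L, i - half); b <- min(n, i + half)
    x[i] >= threshold * max(x[a:b])
  }, logical(1))
  cand <- cand[keep]
  cand <- enforce_separation(cand, x[cand], round(0.3 * fs))
  beat_train(ppg$t0 + (cand - 1L) / fs)
}

# Dominant pulse frequency in [0.5, 3] Hz from the periodogram, used to turn
# "peaks per segment" into a segment duration. NA when no power in band.
dominant_rate <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 16L || !any(x != 0)) return(NA_real_)
  spec <- Mod(stats::fft(x)[seq_len(n %/% 2 + 1L)]) ^ 2
  freqs <- (seq_along(spec) - 1L) * fs / n
  band <- freqs >= 0.5 & freqs <= 3
  if (!any(band)) return(NA_real_)
  freqs[band][which.max(spec[band])]
}

#' Automatic multiscale-based peak detection (AMPD)
#'
#' Builds the local-maxima scalogram of each segment: sample `i` is a
#' scale-`k` maximum when it exceeds both neighbors at lag `k`. The scale
#' with the most maxima fixes the window `lambda`, and peaks are the samples
#' that are maxima at every scale up to `lambda`. Long signals are split
#' into segments of roughly `expected_peaks_per_segment` pulses (about 20 s
#' at typical rates) with 50% overlap; duplicate detections within 0.1 s are
#' merged, keeping the earlier one.
#'
#' @param ppg A demodulated PPG [uniform_signal()].
#' @param expected_peaks_per_segment Target pulses per segment (default 30).
#' @return A [beat_train()] of systolic-peak times.
#' @export
ampd <- function(ppg, expected_peaks_per_segment = 30) {
  stopifnot(inherits(ppg, "uniform_signal"))
  x <- ppg$values
  n <- length(x)
  fs <- ppg$fs
  if (n < 4L) stop("AMPD needs at least 4 samples")
  rate <- dominant_rate(x, fs)
  seg_dur <- if (is.finite(rate)) expected_peaks_per_segment / rate else 20
  seg_len <- min(n, max(4L, round(seg_dur * fs)))
  hop <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, max(1L, n - seg_len + 1L), by = hop)
  if (starts[length(starts)] + seg_len - 1L < n)
    starts <- c(starts, n - seg_len + 1L)

  all_idx <- integer(0)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    m <- length(seg)
    tt <- seq_len(m)
    seg <- seg - stats::lm.fit(cbind(1, tt), seg)$fitted.values
    kmax <- max(1L, (m + 1L) %/% 2L - 1L)
    # pass 1: count scale-k maxima to choose lambda
    gamma <- integer(kmax)
    for (k in seq_len(kmax)) {
      i <- (k + 1L):(m - k)
      gamma[k] <- sum(seg[i] > seg[i - k] & seg[i] > seg[i + k])
    }
    lambda <- which.max(gamma)
    # pass 2: samples that are maxima at every scale <= lambda
    ok <- rep(TRUE, m)
    for (k in seq_len(lambda)) {
      i <- (k + 1L):(m - k)
      cond <- rep(FALSE, m)
      cond[i] <- seg[i] > seg[i - k] & seg[i] > seg[i + k]
      ok <- ok & cond
    }
    all_idx <- c(all_idx, s0 - 1L + which(ok))
  }
  all_idx <- sort(unique(all_idx))
  if (length(all_idx) > 1L) {
    # merge overlap duplicates within 0.1 s, keeping the earlier detection
    min_gap <- 0.1 * fs
    keep <- c(TRUE, diff(all_idx) >= min_gap)
    all_idx <- all_idx[keep]
  }
  beat_train(ppg$t0 + (all_idx - 1L) / fs)
}

#' Slope sum function parameters
#'
#' @param w Analysis window length in ms (default 128).
#' @param init_seconds Seconds of signal defining the initial threshold
#'   (default 10).
#' @param update_fraction Fraction of the per-pulse SSF maximum used as the
#'   updated threshold (default 0.40).
#' @return A list of class `ssf_params`.
#' @export
ssf_params <- function(w = 128, init_seconds = 10, update_fraction = 0.40) {
  if (w <= 0) stop("w must be positive")
  if (update_fraction <= 0 || update_fraction >= 1)
    stop("update_fraction must lie in (0, 1)")
  structure(list(w = w, init_seconds = init_seconds,
                 update_fraction = update_fraction), class = "ssf_params")
}

#' Slope sum function transform
#'
#' At each sample, the sum of positive first differences over the trailing
#' window of `w` ms, accentuating pulse upstrokes. Leading partial windows
#' use the available samples.
#'
#' @param ppg A [uniform_signal()].
#' @param params An [ssf_params()] object.
#' @return A non-negative [uniform_signal()] of the same length.
#' @export
ssf_transform <- function(ppg, params = ssf_params()) {
  stopifnot(inherits(ppg, "uniform_signal"))
  x <- ppg$values
  n <- length(x)
  fs <- ppg$fs
  w_samp <- max(1L, round(params$w / 1000 * fs))
  pos <- c(0, pmax(diff(x), 0))
  cs <- c(0, cumsum(pos))
  lo <- pmax(0L, seq_len(n) - w_samp)
  ssf <- cs[seq_len(n) + 1L] - cs[lo + 1L]
  uniform_signal(ssf, fs = fs, t0 = ppg$t0)
}

#' Slope-sum-function pulse detection
#'
#' Computes the SSF of the signal (optionally reflected upside-down for
#' devices that record the PPG inverted), declares a pulse onset whenever
#' the SSF crosses its threshold upward, and refines each onset to the
#' systolic-peak maximum of the peak-up signal within the following 0.3 s.
#' The initial threshold is the mean SSF over the first `init_seconds`; after
#' each pulse it becomes `update_fraction` times the SSF maximum within that
#' pulse. A 0.3 s refractory period separates onsets.
#'
#' @param ppg A demodulated PPG [uniform_signal()], at least `init_seconds`
#'   long.
#' @param params An [ssf_params()] object.
#' @param reflect Negate the signal first (for inverted device polarity)?
#' @return A [beat_train()] of systolic-peak times.
#' @export
ssf_detect <- function(ppg, params = ssf_params(), reflect = FALSE) {
  stopifnot(inherits(ppg, "uniform_signal"))
  fs <- ppg$fs
  n <- length(ppg$values)
  if (n < params$init_seconds * fs)
    stop("signal shorter than init_seconds; cannot set the initial threshold")
  y <- if (reflect) -ppg$values else ppg$values
  ys <- uniform_signal(y, fs = fs, t0 = ppg$t0)
  ssf <- ssf_transform(ys, params)$values
  init_n <- round(params$init_seconds * fs)
  thr <- mean(ssf[seq_len(init_n)])
  refr <- round(0.3 * fs)
  search <- round(0.3 * fs)

  onsets <- integer(0)
  peaks <- integer(0)
  last_onset <- -Inf
  i <- 2L
  while (i <= n) {
    if (ssf[i] > thr && ssf[i - 1L] <= thr && (i - last_onset) >= refr) {
      hi <- min(n, i + search)
      pulse_max <- max(ssf[i:hi])
      if (pulse_max > 0) {
        onsets <- c(onsets, i)
        # the onset may fire a shade after the systolic maximum when the
        # threshold is high, so allow a half-window look-back
        lo <- max(1L, i - search %/% 2L)
        pk <- lo + which.max(y[lo:hi]) - 1L
        peaks <- c(peaks, pk)
        thr <- params$update_fraction * pulse_max
        last_onset <- i
      }
    }
    i <- i + 1L
  }
  if (!length(peaks)) return(beat_train(numeric(0)))
  peaks <- unique(peaks)
  peaks <- enforce_separation(peaks, y[peaks], refr)
  beat_train(ppg$t0 + (peaks - 1L) / fs)
}

#' Dispatch helper over the four beat detectors
#'
#' @param signal A filtered (and for PPG, demodulated) [uniform_signal()].
#' @param method One of `"pantompkins"`, `"pda"`, `"ampd"`, `"ssf"`.
#' @param ... Passed to the selected detector.
#' @return A [beat_train()].
#' @export
detect_beats <- function(signal,
                         method = c("pda", "ampd", "ssf", "pantompkins"),
                         ...) {
  method <- match.arg(method)
  switch(method,
         pantompkins = pan_tompkins(signal),
         pda = pda(signal, ...),
         ampd = ampd(signal, ...),
         ssf = ssf_detect(signal, ...))
}
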