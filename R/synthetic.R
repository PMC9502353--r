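#' Parameters of the synthetic beat process
#'
#' Instantaneous heart rate `r(t) = mean_hr + lf_amp sin(2 pi lf_freq t) +
#' hf_amp sin(2 pi hf_freq t)` (bpm), modulated in the low-frequency
#' (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) autonomic bands.
#'
#' @param duration Recording length in seconds.
#' @param mean_hr Mean heart rate in bpm.
#' @param lf_freq,lf_amp LF modulator frequency (Hz) and amplitude (bpm).
#' @param hf_freq,hf_amp HF modulator frequency (Hz) and amplitude (bpm).
#' @param jitter_sd Gaussian beat-timing jitter SD in seconds.
#' @param seed Integer seed making the train reproducible.
#' @return A list of class `beat_process_params`.
#' @export
beat_process_params <- function(duration = 300, mean_hr = 70,
                                lf_freq = 0.1, lf_amp = 2,
                                hf_freq = 0.25, hf_amp = 3,
                                jitter_sd = 0.002, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (mean_hr - lf_amp - hf_amp <= 40)
    stop("rate guard violated: mean_hr - lf_amp - hf_amp must exceed 40 bpm")
  structure(list(duration = duration, mean_hr = mean_hr,
                 lf_freq = lf_freq, lf_amp = lf_amp,
                 hf_freq = hf_freq, hf_amp = hf_amp,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "beat_process_params")
}

#' Simulate a beat train by integral pulse frequency modulation
#'
#' A beat is emitted whenever the integral of `r(t)/60` crosses the next
#' integer; optional Gaussian timing jitter is added afterwards. The
#' returned rate function is the ground truth for the variability chain.
#'
#' @param params A [beat_process_params()].
#' @return A list with `beats` (a [beat_train()]) and `rate` (function of
#'   time returning bpm).
#' @export
simulate_beats <- function(params = beat_process_params()) {
  stopifnot(inherits(params, "beat_process_params"))
  p <- params
  rate <- function(t) {
    p$mean_hr + p$lf_amp * sin(2 * pi * p$lf_freq * t) +
      p$hf_amp * sin(2 * pi * p$hf_freq * t)
  }
  # closed-form integral of r(t)/60: monotone, inverted on a fine grid
  Lambda <- function(t) {
    v <- p$mean_hr * t / 60
    if (p$lf_amp > 0 && p$lf_freq > 0)
      v <- v - p$lf_amp * (cos(2 * pi * p$lf_freq * t) - 1) /
        (60 * 2 * pi * p$lf_freq)
    if (p$hf_amp > 0 && p$hf_freq > 0)
      v <- v - p$hf_amp * (cos(2 * pi * p$hf_freq * t) - 1) /
        (60 * 2 * pi * p$hf_freq)
    v
  }
  grid <- seq(0, p$duration, by = 0.005)
  lam <- Lambda(grid)
  n_beats <- floor(lam[length(lam)])
  if (n_beats < 1L) stop("duration too short to emit a beat")
  times <- stats::approx(lam, grid, xout = seq_len(n_beats))$y
  if (p$jitter_sd > 0) {
    set.seed(p$seed)
    times <- times + stats::rnorm(n_beats, 0, p$jitter_sd)
    times <- sort(times)
    # jitter must not break strict ordering
    while (any(diff(times) <= 0))
      times <- times[c(TRUE, diff(times) > 0)]
  }
  list(beats = beat_train(times), rate = rate)
}

# Discretized PPG pulse template: gamma-like systolic rise/decay with a
# secondary diastolic bump at 0.35 of the systolic amplitude.
ppg_pulse_template <- function(fs) {
  t <- seq(0, 0.7, by = 1 / fs)
  a <- 0.2; alpha <- 3
  systolic <- (t / a) ^ alpha * exp(alpha * (1 - t / a))
  diastolic <- 0.35 * exp(-(t - 0.45) ^ 2 / (2 * 0.06 ^ 2))
  v <- systolic + diastolic
  v / max(v)
}

# Superpose a template at each beat, peak landing at beat + offset.
superpose <- function(times, template, peak_idx, fs, duration, t0 = 0,
                      offset = 0) {
  n <- floor(duration * fs) + 1L
  out <- numeric(n)
  for (bt in times) {
    center <- round((bt + offset - t0) * fs) + 1L
    i0 <- center - peak_idx + 1L
    src <- seq_along(template)
    dst <- i0 + src - 1L
    ok <- dst >= 1L & dst <= n
    out[dst[ok]] <- out[dst[ok]] + template[src[ok]]
  }
  out
}

#' Synthesize a PPG waveform from a beat train
#'
#' Superposition of a single-lobe pulse template (systolic and diastolic
#' phases) at each beat time; the systolic peak lands at beat time plus a
#' constant pulse-transit offset.
#'
#' @param beats A [beat_train()].
#' @param fs Sampling rate in Hz (default 25).
#' @param duration Output length in seconds (default: last beat + 1 s).
#' @param offset Pulse-transit offset in seconds (default 0.25).
#' @param template Optional custom pulse template (numeric, dominant single
#'   maximum).
#' @return A [uniform_signal()].
#' @export
synth_ppg <- function(beats, fs = 25, duration = NULL, offset = 0.25,
                      template = NULL) {
  stopifnot(inherits(beats, "beat_train"))
  if (is.null(duration))
    duration <- if (length(beats$times)) max(beats$times) + 1 else 1
  if (is.null(template)) template <- ppg_pulse_template(fs)
  peak_idx <- which.max(template)
  if (length(beats$times) > 1L &&
      length(template) / fs > stats::median(diff(beats$times)))
    warning("pulse template longer than the median beat interval; pulses overlap")
  uniform_signal(superpose(beats$times, template, peak_idx, fs, duration,
                           offset = offset),
                 fs = fs, t0 = 0)
}

# QRS-like biphasic template with small P and T lobes, centered on the R peak.
ecg_beat_template <- function(fs) {
  t <- seq(-0.3, 0.45, by = 1 / fs)
  # QRS width ~90 ms so the dominant energy sits in the 5-15 Hz band
  r <- exp(-(t / 0.02) ^ 2)
  q <- -0.15 * exp(-((t + 0.04) / 0.015) ^ 2)
  s <- -0.25 * exp(-((t - 0.04) / 0.018) ^ 2)
  p <- 0.12 * exp(-((t + 0.18) / 0.03) ^ 2)
  tw <- 0.3 * exp(-((t - 0.25) / 0.05) ^ 2)
  r + q + s + p + tw
}

#' Synthesize an ECG waveform from a beat train
#'
#' Narrow biphasic QRS-like template centered exactly at each beat time,
#' with small P and T lobes.
#'
#' @param beats A [beat_train()].
#' @param fs Sampling rate in Hz (default 130).
#' @param duration Output length in seconds (default: last beat + 1 s).
#' @return A [uniform_signal()].
#' @export
synth_ecg <- function(beats, fs = 130, duration = NULL) {
  stopifnot(inherits(beats, "beat_train"))
  if (is.null(duration))
    duration <- if (length(beats$times)) max(beats$times) + 1 else 1
  template <- ecg_beat_template(fs)
  peak_idx <- which.max(template)
  uniform_signal(superpose(beats$times, template, peak_idx, fs, duration),
                 fs = fs, t0 = 0)
}

#' Artifact regime specification
#'
#' The five laboratory regimes: `none`, `light` (10 s lighting steps), `tap`
#' (biphasic motion transients with brief sensor-contact loss, 1 s periods
#' for the first half and 2 s for the second), `arm` (deep 20 s-period
#' amplitude modulation that can extinguish the pulse, plus slow baseline
#' wander), `breath` (mild additive baseline at the guided breathing rates,
#' 5 then 30 breaths/min; the physiological rate-side effect belongs in the
#' beat process via its HF modulator). All regimes add severity-scaled
#' Gaussian sensor noise.
#'
#' @param regime One of `"none"`, `"light"`, `"tap"`, `"arm"`, `"breath"`.
#' @param severity Non-negative scalar multiplying the regime's nominal
#'   amplitudes (0 leaves the signal untouched).
#' @param seed Integer seed for the sensor-noise component.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(regime = c("none", "light", "tap", "arm", "breath"),
                          severity = 1, seed = 1L) {
  regime <- match.arg(regime)
  if (severity < 0) stop("severity must be >= 0")
  structure(list(regime = regime, severity = severity,
                 seed = as.integer(seed)), class = "artifact_spec")
}

#' Inject laboratory artifacts into a waveform
#'
#' Applies the additive/multiplicative disturbance of the chosen regime plus
#' severity-scaled Gaussian sensor noise; `severity = 0` is the identity.
#'
#' @param signal A [uniform_signal()].
#' @param spec An [artifact_spec()].
#' @return The corrupted [uniform_signal()].
#' @export
inject_artifacts <- function(signal, spec = artifact_spec()) {
  stopifnot(inherits(signal, "uniform_signal"), inherits(spec, "artifact_spec"))
  x <- signal$values
  if (spec$severity == 0) return(signal)
  tt <- signal_times(signal)
  s <- stats::sd(x)
  if (s == 0) s <- 1
  sev <- spec$severity
  tap_count <- NA_integer_
  half_t <- signal$t0 + (tt[length(tt)] - signal$t0) / 2
  x <- switch(spec$regime,
    none = x,
    light = {
      sq <- ifelse(((tt - signal$t0) %/% 10) %% 2 == 0, 1, -1)
      x + sev * s * sq
    },
    tap = {
      span <- tt[length(tt)] - signal$t0
      rel_t <- c(seq(1, span / 2, by = 1),
                 seq(span / 2 + 2, span, by = 2))
      # a tap briefly decouples the sensor (blanking) and superposes a
      # biphasic motion transient with energy inside the pulse band
      fs <- signal$fs
      k <- seq(-0.32, 0.32, by = 1 / fs)
      shape <- -(k / 0.08) * exp(-(k / 0.08) ^ 2 / 2)
      blank <- rep(1, length(x))
      depth <- max(1 - 0.98 * sev, 0.02)
      bh <- round(0.25 * fs)
      applied <- 0L
      centers <- integer(0)
      for (st in rel_t) {
        i0 <- round(st * fs) + 1L
        if (i0 >= 1L && i0 <= length(x)) {
          applied <- applied + 1L
          centers <- c(centers, i0)
          blank[max(1L, i0 - bh):min(length(x), i0 + bh)] <- depth
        }
      }
      y <- x * blank
      for (i0 in centers) {
        i <- i0 + seq_along(k) - (length(k) + 1L) %/% 2L
        ok <- i >= 1L & i <= length(y)
        y[i[ok]] <- y[i[ok]] + 4 * sev * s * shape[ok]
      }
      tap_count <- applied
      y
    },
    arm = {
      # raising the arm drains the wrist: deep amplitude modulation that can
      # extinguish the pulse entirely, plus slow hydrostatic baseline wander
      env <- pmax(1 + sev * sin(2 * pi * (tt - signal$t0) / 20), 0)
      wander <- 2 * sev * s * sin(2 * pi * 0.05 * (tt - signal$t0))
      x * env + wander
    },
    breath = {
      f <- ifelse(tt <= half_t, 5 / 60, 30 / 60)
      x + 0.5 * sev * s * sin(2 * pi * f * (tt - signal$t0))
    })
  set.seed(spec$seed)
  x <- x + stats::rnorm(length(x), 0, 0.05 * sev * s)
  out <- uniform_signal(x, fs = signal$fs, t0 = signal$t0)
  if (spec$regime == "tap") attr(out, "events") <- list(taps = tap_count)
  out
}

#' One-call synthetic recording
#'
#' Generates a beat train, the paired PPG (25 Hz) and ECG (130 Hz)
#' waveforms, and applies an artifact regime to the PPG (the chest-strap ECG
#' stays clean apart from mild sensor noise).
#'
#' @param params A [beat_process_params()].
#' @param regime Artifact regime for the PPG (see [artifact_spec()]).
#' @param severity Artifact severity.
#' @param ppg_fs,ecg_fs Sampling rates in Hz.
#' @return A list with `beats`, `rate`, `ppg`, `ecg`.
#' @export
simulate_recording <- function(params = beat_process_params(),
                               regime = "none", severity = 1,
                               ppg_fs = 25, ecg_fs = 130) {
  sim <- simulate_beats(params)
  dur <- params$duration
  ppg <- synth_ppg(sim$beats, fs = ppg_fs, duration = dur)
  ecg <- synth_ecg(sim$beats, fs = ecg_fs, duration = dur)
  ppg <- inject_artifacts(ppg, artifact_spec(regime, severity,
                                             seed = params$seed + 1L))
  ecg <- inject_artifacts(ecg, artifact_spec("none", severity = 0.1,
                                             seed = params$seed + 2L))
  list(beats = sim$beats, rate = sim$rate, ppg = ppg, ecg = ecg)
}
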