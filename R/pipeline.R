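#' Default pipeline configuration
#'
#' Nested list of every stage toggle and parameter of the PPG -> PRV and
#' ECG -> HRV chains. Unknown keys are rejected when a configuration is
#' loaded, and a configuration round-trips unchanged through its YAML file.
#'
#' @param ... Named overrides; nested lists are merged by key (e.g.
#'   `ppg = list(detector = "ssf")`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    input = list(ppg_path = NULL, ecg_path = NULL, time_unit = "s"),
    simulate = list(enabled = TRUE, duration = 300, mean_hr = 70,
                    lf_freq = 0.1, lf_amp = 2, hf_freq = 0.25, hf_amp = 3,
                    jitter_sd = 0.002, regime = "none", severity = 1),
    ppg = list(wavelet = "coif1", demod_method = "hilbert",
               demod_window = NULL, demod_p = 0.3, detect_fs = 250,
               detector = "pda", pda_threshold = 0.8, ampd_peaks = 30,
               ssf_w = 128, ssf_init = 10, ssf_update = 0.4,
               ssf_reflect = FALSE),
    ecg = list(wavelet = "sym4", detect_fs = 260),
    post = list(screen = TRUE, lo = 0.3, hi = 1.5,
                outlier = TRUE, outlier_window = 25, outlier_k = 3,
                ar = TRUE, ar_window = 25, ar_order = 8, ar_k = 1),
    resample = list(mid_fs = 10, cutoff = 0.5, out_fs = 1),
    welch = list(window_s = 30, overlap_samples = 25),
    out_dir = NULL)
  structure(merge_config(cfg, list(...)), class = "pipeline_config")
}

# Merge overrides into defaults, rejecting keys the defaults do not know.
merge_config <- function(base, override, path = "") {
  if (!length(override)) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == ""))
    stop("configuration overrides must be named")
  for (nm in nms) {
    full <- paste0(path, nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(full, "."))
    } else {
      base[nm] <- override[nm]   # keeps explicit NULLs
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with (a subset of) [pipeline_config()] keys.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Crop `a` to the time span shared with `b` and spline-sample `b` onto the
# cropped grid of `a`, so the two variability series are length-matched.
align_uniform <- function(a, b) {
  ta <- a$t0 + (seq_along(a$values) - 1) / a$fs_v
  tb <- b$t0 + (seq_along(b$values) - 1) / b$fs_v
  t_start <- max(ta[1], tb[1])
  t_end <- min(ta[length(ta)], tb[length(tb)])
  if (t_end - t_start < 4 / a$fs_v) stop("series share too little time")
  keep <- ta >= t_start - 1e-9 & ta <= t_end + 1e-9
  fb <- stats::splinefun(tb, b$values, method = "fmm")
  list(a = uniform_variability(a$values[keep], a$fs_v, ta[keep][1]),
       b = uniform_variability(fb(ta[keep]), b$fs_v, ta[keep][1]))
}

# Beats -> screened/corrected interval series -> uniform series.
variability_chain <- function(beats, cfg, is_prv, events) {
  iv <- beats_to_intervals(beats)
  raw <- iv
  if (cfg$post$screen) {
    iv <- screen_physiological(iv, screening_bounds(cfg$post$lo, cfg$post$hi))
    events$log(sprintf("%s screening: %d merged, %d split, %d residual",
                       if (is_prv) "PRV" else "HRV",
                       attr(iv, "events")$merged, attr(iv, "events")$split,
                       attr(iv, "events")$residual))
  }
  if (is_prv && cfg$post$outlier) {
    iv <- correct_outliers_local(iv, cfg$post$outlier_window,
                                 cfg$post$outlier_k)
    events$log(sprintf("PRV local-statistics correction: %d merged, %d split",
                       attr(iv, "events")$merged, attr(iv, "events")$split))
  }
  u <- to_uniform(iv, cfg$resample$mid_fs, cfg$resample$cutoff,
                  cfg$resample$out_fs)
  if (is_prv && cfg$post$ar) {
    u <- ar_correct(u, ar_params(cfg$post$ar_window, cfg$post$ar_order,
                                 cfg$post$ar_k))
    events$log(sprintf("PRV AR correction: %d samples replaced (%d skipped)",
                       length(attr(u, "events")$replaced),
                       attr(u, "events")$skipped))
  }
  list(raw = raw, intervals = iv, uniform = u)
}

#' Run the full PPG/ECG processing pipeline
#'
#' Executes both flows: ECG -> wavelet filter -> Pan-Tompkins -> HRV, and
#' PPG -> wavelet filter -> amplitude demodulation -> systolic-peak detector
#' -> PRV, each followed by the configured post-processing (physiological
#' screening, local-statistics outlier correction, uniform resampling with
#' 0.5 Hz low-pass, AR correction for the PRV), and compares the two chains
#' (DTW + aligned Pearson on the raw interval sequences, RRMSE on the
#' uniform series, Welch PSDs). Inputs are either read from CSV or simulated
#' with ground truth.
#'
#' @param config A [pipeline_config()].
#' @return A list with `report` (a `comparison_report`), `hrv`, `prv`
#'   (chain outputs: `raw`, `intervals`, `uniform`), `beats_ecg`,
#'   `beats_ppg`, `psd_hrv`, `psd_prv`, `truth` (simulation ground truth or
#'   `NULL`), and `events` (correction-event log, character vector).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  env <- new.env()
  env$messages <- character(0)
  events <- list(log = function(msg) env$messages <- c(env$messages, msg))

  truth <- NULL
  if (!is.null(cfg$input$ppg_path) && !is.null(cfg$input$ecg_path)) {
    ppg <- read_signal(cfg$input$ppg_path, fs = 25,
                       time_unit = cfg$input$time_unit)
    ecg <- read_signal(cfg$input$ecg_path, fs = 130,
                       time_unit = cfg$input$time_unit)
  } else if (isTRUE(cfg$simulate$enabled)) {
    params <- beat_process_params(
      duration = cfg$simulate$duration, mean_hr = cfg$simulate$mean_hr,
      lf_freq = cfg$simulate$lf_freq, lf_amp = cfg$simulate$lf_amp,
      hf_freq = cfg$simulate$hf_freq, hf_amp = cfg$simulate$hf_amp,
      jitter_sd = cfg$simulate$jitter_sd, seed = cfg$seed)
    rec <- simulate_recording(params, regime = cfg$simulate$regime,
                              severity = cfg$simulate$severity)
    ppg <- rec$ppg
    ecg <- rec$ecg
    truth <- list(beats = rec$beats, rate = rec$rate)
    events$log(sprintf("simulated %g s, regime %s, severity %g, seed %d",
                       cfg$simulate$duration, cfg$simulate$regime,
                       cfg$simulate$severity, cfg$seed))
  } else {
    stop("no input: provide input paths or enable simulation")
  }

  # ECG reference chain
  ecg_f <- filter_ecg(ecg, wavelet = cfg$ecg$wavelet)
  ecg_d <- if (cfg$ecg$detect_fs > ecg$fs)
    resample_cubic(ecg_f, cfg$ecg$detect_fs) else ecg_f
  beats_ecg <- pan_tompkins(ecg_d)
  hrv <- variability_chain(beats_ecg, cfg, is_prv = FALSE, events)

  # PPG chain
  ppg_f <- filter_ppg(ppg, wavelet = cfg$ppg$wavelet)
  ppg_dm <- demodulate(ppg_f, method = cfg$ppg$demod_method,
                       window_len = cfg$ppg$demod_window, P = cfg$ppg$demod_p)
  ppg_d <- if (cfg$ppg$detect_fs > ppg$fs)
    resample_cubic(ppg_dm, cfg$ppg$detect_fs) else ppg_dm
  beats_ppg <- switch(cfg$ppg$detector,
    pda = pda(ppg_d, threshold = cfg$ppg$pda_threshold),
    ampd = ampd(ppg_d, expected_peaks_per_segment = cfg$ppg$ampd_peaks),
    ssf = ssf_detect(ppg_d,
                     ssf_params(cfg$ppg$ssf_w, cfg$ppg$ssf_init,
                                cfg$ppg$ssf_update),
                     reflect = cfg$ppg$ssf_reflect),
    stop("unknown detector: ", cfg$ppg$detector))
  prv <- variability_chain(beats_ppg, cfg, is_prv = TRUE, events)

  al <- align_uniform(prv$uniform, hrv$uniform)
  report <- compare_variability(prv$intervals, hrv$intervals, al$a, al$b)

  psd_hrv <- psd_prv <- NULL
  seg <- cfg$welch$window_s * cfg$resample$out_fs
  if (length(al$a$values) >= seg) {
    psd_prv <- welch_psd(al$a, cfg$welch$window_s, cfg$welch$overlap_samples)
    psd_hrv <- welch_psd(al$b, cfg$welch$window_s, cfg$welch$overlap_samples)
  }

  res <- list(report = report, hrv = hrv, prv = prv,
              beats_ecg = beats_ecg, beats_ppg = beats_ppg,
              prv_aligned = al$a, hrv_aligned = al$b,
              psd_hrv = psd_hrv, psd_prv = psd_prv,
              truth = truth, events = env$messages)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_beats(beats_ecg, p("beats_ecg.csv"))
    write_beats(beats_ppg, p("beats_ppg.csv"))
    write_intervals(prv$intervals, p("prv_intervals.csv"))
    write_intervals(hrv$intervals, p("hrv_intervals.csv"))
    write_signal(uniform_signal(al$a$values, al$a$fs_v, al$a$t0),
                 p("prv_uniform.csv"))
    write_signal(uniform_signal(al$b$values, al$b$fs_v, al$b$t0),
                 p("hrv_uniform.csv"))
    jsonlite::write_json(unclass(report), p("report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(env$messages, p("events.log"))
  }
  res
}
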