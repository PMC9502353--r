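test_that("Pan-Tompkins finds every QRS of a clean train at 20 dB SNR", {
  set.seed(30)
  truth <- seq(1, 119, by = 1)                     # 60 bpm
  ecg <- synth_ecg(beat_train(truth), fs = 130, duration = 120)
  noise_sd <- rms(ecg$values) / 10                 # 20 dB
  noisy <- uniform_signal(ecg$values + rnorm(length(ecg$values), 0, noise_sd),
                          fs = 130)
  det <- pan_tompkins(filter_ecg(noisy))
  expect_equal(length(det$times), length(truth))
  expect_lt(max(abs(det$times - truth)), 1.5 / 130)
})

test_that("Pan-Tompkins recovers a halved-amplitude beat via search-back", {
  truth <- seq(1, 119, by = 1)
  tpl_scale <- rep(1, length(truth))
  tpl_scale[60] <- 0.5
  ecg <- synth_ecg(beat_train(truth), fs = 130, duration = 120)
  # rebuild with one attenuated beat
  weak <- synth_ecg(beat_train(truth[60]), fs = 130, duration = 120)
  ecg$values <- ecg$values - 0.5 * weak$values
  det <- pan_tompkins(filter_ecg(ecg))
  expect_equal(length(det$times), length(truth))
  expect_lt(max(abs(det$times - truth)), 2 / 130)
})

test_that("Pan-Tompkins respects the refractory bound on noise", {
  set.seed(31)
  noise <- uniform_signal(rnorm(130 * 2), fs = 130)
  det <- pan_tompkins(noise)
  expect_lte(length(det$times), ceiling(2 / 0.2))
  if (length(det$times) > 1) expect_true(all(diff(det$times) >= 0.2 - 1e-9))
  expect_error(pan_tompkins(uniform_signal(rnorm(100), 130)), "shorter than 2 s")
  expect_error(pan_tompkins(uniform_signal(rnorm(100), 50)), "fs >= 100")
})

test_that("PDA finds clean demodulated pulses and gates small bumps", {
  beats <- beat_train(seq(0.5, 59.5, by = 1))      # 60 bpm, 60 s
  ppg <- synth_ppg(beats, fs = 25, duration = 60)
  dm <- hilbert_demodulate(filter_ppg(ppg))
  det <- pda(dm)
  expect_equal(length(det$times), length(beats$times))
  # all detections within one sample of a true systolic peak (+0.25 s offset)
  err <- vapply(det$times,
                function(x) min(abs(x - (beats$times + 0.25))), 1)
  expect_lt(max(err), 1.5 / 25)

  # a bump at half the local maximum is rejected by the 0.8 gate
  spiky <- dm
  mid <- round(length(dm$values) / 2)
  spiky$values[mid] <- 0.5 * max(dm$values[(mid - 25):(mid + 25)])
  expect_equal(length(pda(spiky)$times), length(beats$times))

  expect_length(pda(uniform_signal(seq_len(100), 25))$times, 0)
  expect_length(pda(uniform_signal(rep(1, 100), 25))$times, 0)
})

test_that("AMPD matches generator truth and basic structural properties", {
  sim <- simulate_beats(beat_process_params(duration = 120, seed = 5))
  ppg <- synth_ppg(sim$beats, fs = 25, duration = 120)
  dm <- hilbert_demodulate(filter_ppg(ppg))
  det <- ampd(dm)
  expect_equal(length(det$times), length(sim$beats$times),
               tolerance = 0.02)
  err <- vapply(det$times,
                function(x) min(abs(x - (sim$beats$times + 0.25))), 1)
  expect_lt(stats::median(err), 1.5 / 25)

  # single triangular pulse in a flat segment: exactly one apex
  tri <- c(rep(0, 40), seq(0, 1, length.out = 10),
           seq(1, 0, length.out = 10)[-1], rep(0, 40))
  one <- ampd(uniform_signal(tri + 1e-9 * seq_along(tri), fs = 25))
  expect_equal(length(one$times), 1)
  expect_equal(one$times, (40 + 10 - 1) / 25, tolerance = 1.5 / 25)

  # scalogram definition forbids adjacent maxima on white noise
  set.seed(32)
  wn <- ampd(uniform_signal(rnorm(500), fs = 25))
  if (length(wn$times) > 1) expect_true(all(diff(wn$times) >= 2 / 25 - 1e-9))
})

test_that("SSF transform matches closed forms", {
  p <- ssf_params(w = 128)
  # strictly decreasing signal: SSF identically zero
  dec <- ssf_transform(uniform_signal(seq(100, 1), fs = 25), p)
  expect_true(all(dec$values == 0))

  # unit step: SSF = 1 on a window-length plateau
  x <- c(rep(0, 50), rep(1, 50))
  st <- ssf_transform(uniform_signal(x, fs = 25), p)
  w_samp <- round(0.128 * 25)
  expect_equal(which(st$values > 0), 51:(50 + w_samp))
  expect_true(all(st$values[st$values > 0] == 1))

  # ramp of slope c per sample: steady-state SSF = c * window samples
  ramp <- ssf_transform(uniform_signal(0.3 * seq_len(100), fs = 25), p)
  expect_equal(unique(round(ramp$values[(w_samp + 1):100], 12)),
               0.3 * w_samp)
})

test_that("SSF detector tracks clean and amplitude-growing pulse trains", {
  # clean demodulated train at 60 bpm: one detection per pulse, interior
  # intervals exact to one sample (the first/last pulse sit on the envelope
  # edge)
  beats <- beat_train(seq(0.5, 299.5, by = 1))
  ppg <- synth_ppg(beats, fs = 25, duration = 300)
  dm <- resample_cubic(hilbert_demodulate(ppg), 250)
  det <- ssf_detect(dm)
  expect_equal(length(det$times), length(beats$times))
  iv <- diff(det$times)
  expect_lt(max(abs(iv[2:(length(iv) - 1)] - 1)), 1.5 / 250)

  # linearly doubling amplitude: threshold adapts, one detection per pulse
  grow <- uniform_signal(ppg$values *
                           seq(1, 2, length.out = length(ppg$values)),
                         fs = 25)
  dg <- resample_cubic(grow, 250)
  detg <- ssf_detect(dg)
  expect_equal(length(detg$times), length(beats$times))

  # full filtered chain on a modulated train still yields one beat per pulse
  sim <- simulate_beats(beat_process_params(duration = 300, seed = 6))
  ppg2 <- synth_ppg(sim$beats, fs = 25, duration = 300)
  dm2 <- resample_cubic(hilbert_demodulate(filter_ppg(ppg2)), 250)
  expect_equal(length(ssf_detect(dm2)$times), length(sim$beats$times))

  expect_length(ssf_detect(uniform_signal(rep(1, 500), fs = 25))$times, 0)
  expect_error(ssf_detect(uniform_signal(rnorm(100), fs = 25)),
               "init_seconds")
})

test_that("detectors return ordered in-span times with refractory gaps", {
  sim <- simulate_beats(beat_process_params(duration = 120, seed = 7))
  ppg <- synth_ppg(sim$beats, fs = 25, duration = 120)
  dm <- resample_cubic(hilbert_demodulate(filter_ppg(ppg)), 250)
  span <- range(signal_times(dm))
  for (m in c("pda", "ampd", "ssf")) {
    det <- detect_beats(dm, m)
    expect_true(all(diff(det$times) > 0))
    expect_true(all(det$times >= span[1] & det$times <= span[2]))
    if (m != "ampd") expect_true(all(diff(det$times) >= 0.3 - 1e-9))
  }
  ecg <- synth_ecg(sim$beats, fs = 130, duration = 120)
  pt <- pan_tompkins(filter_ecg(ecg))
  expect_true(all(diff(pt$times) >= 0.2 - 1e-9))
})

test_that("the three PPG detectors agree on clean data", {
  sim <- simulate_beats(beat_process_params(duration = 300, seed = 8))
  ppg <- synth_ppg(sim$beats, fs = 25, duration = 300)
  dm <- resample_cubic(hilbert_demodulate(filter_ppg(ppg)), 250)
  sets <- lapply(c("pda", "ampd", "ssf"), function(m) detect_beats(dm, m))
  names(sets) <- c("pda", "ampd", "ssf")
  tol <- 1.5 / 250
  pairs <- list(c("pda", "ampd"), c("pda", "ssf"), c("ampd", "ssf"))
  for (p in pairs) {
    a <- sets[[p[1]]]$times
    b <- sets[[p[2]]]$times
    frac <- mean(vapply(a, function(x) min(abs(b - x)) <= tol, TRUE))
    expect_gte(frac, 0.99)
  }
})
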