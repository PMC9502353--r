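test_that("maximal-overlap decomposition keeps length and reconstructs exactly", {
  set.seed(10)
  for (wv in c("sym4", "coif1")) {
    for (rep in 1:10) {
      n <- sample(100:600, 1)
      s <- uniform_signal(rnorm(n), fs = 25)
      d <- modwt(s, wv, levels = 4)
      expect_true(all(vapply(d$details, length, 1L) == n))
      expect_length(d$approximation, n)
      r <- reconstruct(d)
      expect_lt(max(abs(r$values - s$values)) / max(abs(s$values)), 1e-8)
    }
  }
})

test_that("constants live entirely in the approximation", {
  d <- modwt(uniform_signal(rep(3.7, 256), 25), "sym4", 4)
  for (det in d$details) expect_lt(max(abs(det)), 1e-10)
  r <- reconstruct(d, keep_details = integer(0), keep_approximation = TRUE)
  expect_equal(r$values, rep(3.7, 256), tolerance = 1e-9)
})

test_that("reconstruction is linear in the kept components", {
  set.seed(11)
  s <- uniform_signal(rnorm(300), fs = 25)
  d <- modwt(s, "coif1", 4)
  a <- reconstruct(d, keep_details = 1, keep_approximation = FALSE)
  b <- reconstruct(d, keep_details = 2:4, keep_approximation = TRUE)
  expect_lt(max(abs(a$values + b$values - s$values)), 1e-8)
  zero <- reconstruct(d, keep_details = integer(0),
                      keep_approximation = FALSE)
  expect_equal(zero$values, rep(0, 300))
  expect_error(reconstruct(d, keep_details = 7), "within 1")
})

test_that("modwt validates levels and wavelet names", {
  s <- uniform_signal(rnorm(64), 25)
  expect_error(modwt(s, "sym4", 7), "too many levels")
  expect_error(modwt(s, "db97", 3), "unknown wavelet")
})

test_that("band edges follow the dyadic formula and match printed figures", {
  expect_equal(band_edges(25, 4), list(f_lo = 25 / 32, f_hi = 25 / 16))
  expect_equal(truncate2(band_edges(25, 4)$f_lo), 0.78)
  expect_equal(truncate2(band_edges(25, 4)$f_hi), 1.56)
  expect_equal(truncate2(band_edges(25, 3)$f_hi), 3.12)
  # rejected ECG band D1 u D2 at 130 Hz spans 16.25-65 Hz
  expect_equal(band_edges(130, 2)$f_lo, 16.25)
  expect_equal(band_edges(130, 1)$f_hi, 65)
  # approximation after 10 levels at 130 Hz sits below 0.064 Hz
  appr <- band_edges(130, 10, "approximation")
  expect_equal(appr$f_lo, 0)
  expect_lt(appr$f_hi, 0.064)
  # PPG passband in bpm brackets the printed 47-187 range
  expect_equal(ceiling(60 * band_edges(25, 4)$f_lo), 47)
  expect_equal(floor(60 * band_edges(25, 3)$f_hi), 187)
})

test_that("ECG filter rejects drift and mains-band noise but keeps QRS content", {
  t <- seq(0, 300, by = 1 / 130)
  drift <- uniform_signal(sin(2 * pi * 0.01 * t), 130)
  expect_lt(rms(filter_ecg(drift)$values), 0.05 * rms(drift$values))

  tone50 <- uniform_signal(sin(2 * pi * 50 * t), 130)
  expect_lt(rms(filter_ecg(tone50)$values), 0.10 * rms(tone50$values))

  beats <- beat_train(seq(1, 299, by = 1))
  qrs <- synth_ecg(beats, fs = 130, duration = 300)
  filt <- filter_ecg(qrs)
  expect_gt(stats::cor(filt$values, qrs$values), 0.95)
})

test_that("PPG filter keeps the pulse band and rejects wander and fast noise", {
  t <- seq(0, 300, by = 1 / 25)
  wander <- uniform_signal(sin(2 * pi * 0.1 * t), 25)
  expect_lt(rms(filter_ppg(wander)$values), 0.10 * rms(wander$values))

  pulse <- uniform_signal(sin(2 * pi * 1.2 * t), 25)
  expect_gt(rms(filter_ppg(pulse)$values), 0.70 * rms(pulse$values))

  fast <- uniform_signal(sin(2 * pi * 10 * t), 25)
  expect_lt(rms(filter_ppg(fast)$values), 0.10 * rms(fast$values))
})

test_that("band filters are linear operators", {
  set.seed(12)
  x <- uniform_signal(rnorm(2600), 130)
  y <- uniform_signal(rnorm(2600), 130)
  mix <- uniform_signal(2 * x$values - 3 * y$values, 130)
  lhs <- filter_ecg(mix)$values
  rhs <- 2 * filter_ecg(x)$values - 3 * filter_ecg(y)$values
  expect_lt(max(abs(lhs - rhs)), 1e-8)

  xp <- uniform_signal(rnorm(500), 25)
  yp <- uniform_signal(rnorm(500), 25)
  mixp <- uniform_signal(0.5 * xp$values + 4 * yp$values, 25)
  expect_lt(max(abs(filter_ppg(mixp)$values -
                      (0.5 * filter_ppg(xp)$values +
                         4 * filter_ppg(yp)$values))), 1e-8)
})

test_that("filters warn at unexpected sampling rates", {
  s <- uniform_signal(rnorm(4096), 64)
  expect_warning(filter_ppg(s), "tuned for 25 Hz")
  expect_warning(filter_ecg(s), "tuned for 130 Hz")
})
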