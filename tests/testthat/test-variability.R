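mk_iv <- function(durations, start = 10) {
  interval_series(start + cumsum(durations), durations)
}

test_that("physiological screening merges short and splits long intervals", {
  # short interval folded into the following one
  out <- screen_physiological(mk_iv(c(0.8, 0.1, 0.7)))
  expect_equal(out$durations, c(0.8, 0.8))

  # long interval split into halves
  out2 <- screen_physiological(mk_iv(1.6))
  expect_equal(out2$durations, c(0.8, 0.8))
  expect_equal(diff(out2$anchor_times), 0.8)

  # in-bounds series is untouched
  clean <- mk_iv(c(0.8, 0.9, 1.1, 0.6))
  expect_equal(screen_physiological(clean)$durations, clean$durations)

  # trailing short interval merges into its predecessor
  out3 <- screen_physiological(mk_iv(c(0.9, 0.2)))
  expect_equal(out3$durations, 1.1)
})

test_that("screening conserves total duration and reports residuals", {
  set.seed(40)
  dur <- c(runif(50, 0.4, 1.4), 0.05, 2.0, 0.1, 3.4)
  iv <- mk_iv(sample(dur))
  out <- screen_physiological(iv)
  expect_equal(sum(out$durations), sum(iv$durations), tolerance = 1e-9)
  ev <- attr(out, "events")
  expect_gte(ev$merged, 2)
  expect_gte(ev$split, 2)
  # 3.4 s splits to 1.7 s halves, still out of bounds: logged, not reprocessed
  expect_gte(ev$residual, 2)
})

test_that("local-statistics correction fixes isolated outliers", {
  dur <- rep(0.8, 60)
  dur[30] <- 2.0
  out <- correct_outliers_local(mk_iv(dur))
  expect_equal(sum(out$durations), sum(dur), tolerance = 1e-9)
  expect_equal(length(out$durations), 61)
  expect_equal(out$durations[30:31], c(1, 1))
  st <- attr(out, "events")
  expect_equal(st$split, 1)

  # short outlier merges into the successor
  dur2 <- rep(0.8, 60)
  dur2[30] <- 0.35
  out2 <- correct_outliers_local(mk_iv(dur2))
  expect_equal(sum(out2$durations), sum(dur2), tolerance = 1e-9)
  expect_equal(length(out2$durations), 59)
})

test_that("correction leaves i.i.d. Gaussian and constant series alone", {
  set.seed(41)
  dur <- rnorm(10000, mean = 0.85, sd = 0.03)
  out <- correct_outliers_local(mk_iv(dur))
  changed <- attr(out, "events")$merged + attr(out, "events")$split
  expect_lt(changed / length(dur), 0.005)

  const <- mk_iv(rep(0.8, 50))
  outc <- correct_outliers_local(const)
  expect_equal(outc$durations, const$durations)
})

test_that("uniform resampling passes DC and in-band modulation", {
  # constant series stays constant
  const <- mk_iv(rep(0.8, 400))
  u <- to_uniform(const)
  expect_equal(u$fs_v, 1)
  expect_lt(max(abs(u$values - 0.8)), 1e-6)

  # 0.1 Hz modulation survives with its amplitude
  tt <- seq(0.85, 300, by = 0.85)
  dur <- 0.85 + 0.05 * sin(2 * pi * 0.1 * tt)
  u2 <- to_uniform(interval_series(tt, dur))
  tu <- u2$t0 + (seq_along(u2$values) - 1)
  fit <- stats::lm(u2$values ~ sin(2 * pi * 0.1 * tu) + cos(2 * pi * 0.1 * tu))
  amp <- sqrt(sum(stats::coef(fit)[2:3] ^ 2))
  expect_gt(amp, 0.045)
  expect_lt(amp, 0.055)

  expect_error(to_uniform(mk_iv(c(0.8, 0.7, 0.9))), "at least 4")
})

test_that("the low-pass transition separates 0.45 from 0.55 Hz", {
  amp_at <- function(f_mod) {
    tt <- seq(0.4, 300, by = 0.4)          # fast beats so spline tracks
    dur <- 0.4 + 0.02 * sin(2 * pi * f_mod * tt)
    iv <- interval_series(tt, dur)
    u <- to_uniform(iv, mid_fs = 10, cutoff = 0.5, out_fs = 10)
    tu <- u$t0 + (seq_along(u$values) - 1) / 10
    fit <- stats::lm(u$values ~ sin(2 * pi * f_mod * tu) +
                       cos(2 * pi * f_mod * tu))
    sqrt(sum(stats::coef(fit)[2:3] ^ 2))
  }
  pass <- amp_at(0.45)
  stop <- amp_at(0.55)
  expect_gt(pass / stop, 10)
})

test_that("AR correction replaces sparse spikes but spares clean processes", {
  set.seed(42)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.6, -0.3)), 500, sd = 0.05)) + 1
  u <- uniform_variability(x, fs_v = 1)
  out <- ar_correct(u)
  frac <- length(attr(out, "events")$replaced) / (500 - 25)
  expect_lt(frac, 0.40)

  spikes <- c(100, 180, 260, 340, 420)
  xs <- x
  xs[spikes] <- xs[spikes] + 10 * 0.05
  outs <- ar_correct(uniform_variability(xs, fs_v = 1))
  expect_true(all(spikes %in% attr(outs, "events")$replaced))
  expect_lt(max(abs(outs$values[spikes] - x[spikes])), 3 * 0.05)

  # constant series: singular fit path, output equals input
  const <- uniform_variability(rep(0.8, 60), fs_v = 1)
  outc <- ar_correct(const)
  expect_equal(outc$values, const$values)
  expect_gt(attr(outc, "events")$skipped, 0)
  expect_error(ar_correct(uniform_variability(rep(0.8, 10), 1)), "longer")
})

test_that("full post-processing barely changes a clean chain", {
  sim <- simulate_beats(beat_process_params(duration = 300, seed = 43))
  iv <- beats_to_intervals(sim$beats)
  u_plain <- to_uniform(iv)
  iv_post <- correct_outliers_local(screen_physiological(iv))
  u_post <- ar_correct(to_uniform(iv_post))
  n <- min(length(u_plain$values), length(u_post$values))
  expect_lt(rms(u_post$values[1:n] - u_plain$values[1:n]),
            0.01 * rms(u_plain$values[1:n]))
})
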