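fs <- 50

test_that("lowpass preserves the respiration band and kills high frequency", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ctr <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  y <- lowpass_butterworth(sin(2 * pi * 0.25 * t), fs)
  # analytic two-pass Butterworth magnitude at 0.25 Hz is 1 - 6e-13
  expect_gt(max(abs(y[ctr])), 0.99)
  expect_lt(max(abs(y[ctr])), 1.01)
  y5 <- lowpass_butterworth(sin(2 * pi * 5 * t), fs)
  atten_db <- 20 * log10(sqrt(mean(y5[ctr]^2)) / sqrt(0.5))
  expect_lt(atten_db, -60)
  # DC gain 1
  yc <- lowpass_butterworth(rep(2.5, 1000), fs)
  expect_equal(yc, rep(2.5, 1000), tolerance = 1e-4)
  expect_error(lowpass_butterworth(rnorm(20), fs), "too short")
})

test_that("zero-phase filtering introduces no lag", {
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)
  y <- lowpass_butterworth(x, fs)
  expect_equal(cross_correlation_lag(x, y, 100), 0L)
})

test_that("moving_smooth is a centered shrinking-edge moving average", {
  expect_identical(moving_smooth(c(1, 5, 3), 1), c(1, 5, 3))
  expect_equal(moving_smooth(rep(4, 50), 30), rep(4, 50))
  expect_equal(moving_smooth(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_error(moving_smooth(1:5, 6), "exceeds")
})

test_that("measured-rate estimation counts samples per analysis window", {
  rec <- triaxial_recording((0:5249) / 52.5, matrix(0, 5250, 3), 50)
  expect_equal(estimate_measured_rate(rec, 100), 52.5)
  rec2 <- triaxial_recording((0:5999) / 50, matrix(0, 6000, 3), 50)
  expect_equal(estimate_measured_rate(rec2, 120), 50)
  # jittered timestamps, averaged over 10 windows
  jit <- breathclass:::with_seed(4, cumsum(rep(1 / 52.5, 5250) +
                                             rnorm(5250, sd = 1e-4)))
  rec3 <- triaxial_recording(jit - jit[1], matrix(0, 5250, 3), 50)
  expect_lt(abs(estimate_measured_rate(rec3, 10) - 52.5), 0.05)
  expect_error(estimate_measured_rate(rec2, 1000), "window")
})

test_that("the nominal/measured mismatch yields the 0.05 s/s lead", {
  expect_equal(sampling_time_lead(50, 52.5), 0.05)
})

test_that("rational resampling hits exact lengths and preserves tones", {
  expect_equal(unname(best_rational(52.5 / 50)), c(21L, 20L))
  x <- sin(2 * pi * 0.3 * (0:1049) / 52.5)
  y <- rational_resample(x, 52.5, 50)
  expect_length(y, 1000L)
  # dominant DFT bin within one bin of 0.3 Hz
  sp <- Mod(fft(y - mean(y)))[1:500]
  f_dom <- (which.max(sp) - 1) * 50 / length(y)
  expect_lt(abs(f_dom - 0.3), 50 / length(y) + 1e-9)
  expect_identical(rational_resample(x, 50, 50), x)
  # peak count unchanged by 52.5 -> 50 resampling
  expect_equal(oracle_peak_count(y), oracle_peak_count(x))
})

test_that("cross-correlation lag matches an exhaustive scan oracle", {
  a <- sin(2 * pi * 0.25 * (0:999) / fs)
  b <- c(rep(0, 25), a)[1:1000]
  expect_equal(cross_correlation_lag(a, b, 60), 25L)
  expect_equal(cross_correlation_lag(a, a, 60), 0L)
  # noisy delayed copy at SNR 10
  noisy <- b + breathclass:::with_seed(8, rnorm(1000, sd = sd(a) / sqrt(10)))
  lag <- cross_correlation_lag(a, noisy, 60)
  expect_lte(abs(lag - 25L), 1L)
  expect_equal(lag, oracle_best_lag(a, noisy, 60))
  expect_error(cross_correlation_lag(rep(1, 100), a[1:100], 10),
               "zero-variance")
})

test_that("respiration_rate counts gated maxima per window", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  est <- respiration_rate(sin(2 * pi * 0.25 * t), fs, 60)
  expect_equal(est$rpm, 15)
  expect_equal(est$rpm, 60 * length(est$peak_indices) / est$window_s)
  expect_equal(respiration_rate(rep(0, 3000), fs, 60)$rpm, 0)
  expect_error(respiration_rate(numeric(0), fs), "empty")
  expect_error(respiration_rate(rnorm(100), fs, 60), "spans")
})

test_that("rate recovery within 1 breath/window across all six patterns", {
  for (p in breath_patterns()) {
    spec0 <- pattern_spec(p, noise_sd = 0)
    spec <- pattern_spec(p, noise_sd = 0.05 * spec0$amplitude)
    wf <- generate_breath_waveform(spec, 60, fs, seed = 3)
    filt <- lowpass_butterworth(wf$series, fs)
    est <- respiration_rate(filt, fs, 60)
    truth <- length(wf$peak_times)
    expect_lte(abs(est$rpm - truth), 1, label = p)
  }
})

test_that("respiration rate is invariant to 52.5 -> 50 Hz resampling", {
  spec <- pattern_spec("normal", noise_sd = 0.05)
  wf <- generate_breath_waveform(spec, 60, 52.5, seed = 6)
  filt <- lowpass_butterworth(wf$series, 52.5)
  rpm_native <- respiration_rate(filt, 52.5, 60)$rpm
  res <- rational_resample(filt, 52.5, 50)
  rpm_resampled <- respiration_rate(res, 50, 60)$rpm
  expect_lte(abs(rpm_native - rpm_resampled), 1)
})

test_that("recording invariants are enforced", {
  expect_error(triaxial_recording(c(0, 0.1, 0.1), matrix(0, 3, 3), 50),
               "increasing")
  expect_error(triaxial_recording(0:1, matrix(0, 2, 2), 50), "3 columns")
})
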