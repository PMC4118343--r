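test_that("pattern_spec validates protocol constraints", {
  expect_s3_class(pattern_spec("normal"), "pattern_spec")
  expect_error(pattern_spec("tachypnea", rate_rpm = 18), "> 20")
  expect_error(pattern_spec("bradapnea", rate_rpm = 14), "< 12")
  expect_error(pattern_spec("cheyne_stokes", apnea_s = 2), ">= 3")
  expect_error(pattern_spec("sighing"))
})

test_that("waveform peak counts match rate x duration for regular patterns", {
  wf <- generate_breath_waveform(
    pattern_spec("normal", rate_rpm = 15, noise_sd = 0), 60, 50)
  expect_length(wf$peak_times, 15L)
  expect_equal(length(wf$series), 60 * 50)
  # property: count/duration * 60 ~ rate for all non-apneic patterns
  for (p in c("normal", "bradapnea", "tachypnea", "kussmaul")) {
    spec <- pattern_spec(p, noise_sd = 0)
    wf <- generate_breath_waveform(spec, 90, 50)
    expect_lt(abs(length(wf$peak_times) / 90 * 60 - spec$rate_rpm), 1 + 1e-9,
              label = p)
  }
})

test_that("waveform generator rejects bad arguments", {
  sp <- pattern_spec("normal")
  expect_error(generate_breath_waveform(sp, -5, 50))
  expect_error(generate_breath_waveform(sp, 60, 0))
})

test_that("apneic patterns have flat apnea segments of the stated length", {
  sp <- pattern_spec("biots", burst_breaths = 4, apnea_s = 4, noise_sd = 0)
  wf <- generate_breath_waveform(sp, 60, 50)
  # zero-variance runs in the noiseless component
  z <- rle(wf$clean == 0)
  apnea_runs <- z$lengths[z$values]
  apnea_runs <- apnea_runs[apnea_runs > 2]   # skip breath-boundary zeros
  expect_true(any(apnea_runs >= 4 * 50 - 1))
  expect_true(all(wf$clean[wf$clean == 0] == 0))  # exactly flat

  sp2 <- pattern_spec("cheyne_stokes", apnea_s = 4, noise_sd = 0)
  wf2 <- generate_breath_waveform(sp2, 120, 50)
  z2 <- rle(wf2$clean == 0)
  expect_true(any(z2$lengths[z2$values] >= 4 * 50 - 1))
})

test_that("ground-truth peaks agree with an independent peak-count oracle", {
  for (p in breath_patterns()) {
    spec <- pattern_spec(p, noise_sd = 0)
    wf <- generate_breath_waveform(spec, 120, 50, seed = 1)
    expect_equal(oracle_peak_count(wf$clean), length(wf$peak_times),
                 label = p)
  }
  # the spec'd Cheyne-Stokes case explicitly
  wf <- generate_breath_waveform(
    pattern_spec("cheyne_stokes", rate_rpm = 30, envelope_period_s = 20,
                 apnea_s = 4, noise_sd = 0), 120, 50, seed = 1)
  expect_equal(oracle_peak_count(wf$clean), length(wf$peak_times))
})

test_that("waveform generation is seed-deterministic", {
  sp <- pattern_spec("normal", noise_sd = 0.05)
  a <- generate_breath_waveform(sp, 30, 50, seed = 9)
  b <- generate_breath_waveform(sp, 30, 50, seed = 9)
  c <- generate_breath_waveform(sp, 30, 50, seed = 10)
  expect_identical(a$series, b$series)
  expect_false(identical(a$series, c$series))
})

test_that("accelerometer projection obeys the stated forward model", {
  wf <- generate_breath_waveform(pattern_spec("normal", noise_sd = 0), 120, 50)
  sens0 <- sensor_model(respiratory_axis_mix = c(0, 0, 0), noise_sd_g = 0)
  rec0 <- project_to_accelerometer(wf, sens0)
  # zero mix, zero noise, identity calibration -> pure gravity DC
  expect_equal(unname(rec0$samples),
               matrix(rep(c(0, 0, 1), each = nrow(rec0$samples)), ncol = 3),
               tolerance = 1e-12)
  # 120 s at measured 52.5 Hz -> 6300 samples (6000 at nominal 50)
  expect_equal(nrow(rec0$samples), 6300L)
  expect_equal(length(wf$series), 6000L)
})

test_that("projection distortion round-trips through calibration fitting", {
  Xstar <- rbind(matrix(c(1.02, 0.01, 0, 0.02, 0.98, 0.01, 0, 0.01, 1.05),
                        3, 3, byrow = TRUE),
                 c(0.10, -0.05, 0.02))
  truth <- calibration_model(Xstar)
  batch <- generate_stationary_batch(truth, noise_sd_g = 0)
  fit <- fit_calibration(batch)
  expect_lt(max(abs(fit$params - Xstar)), 1e-6)
})

test_that("stationary batch construction matches its definition", {
  b <- generate_stationary_batch(calibration_model(), 0)
  expect_equal(b$raw, b$gravity, tolerance = 1e-12)
  off <- calibration_model(rbind(diag(3), c(0.1, -0.2, 0.05)))
  b2 <- generate_stationary_batch(off, 0)
  expect_equal(b2$raw, sweep(b2$gravity, 2, c(0.1, -0.2, 0.05)),
               tolerance = 1e-12)
  n1 <- generate_stationary_batch(off, 0.01, seed = 3)
  n2 <- generate_stationary_batch(off, 0.01, seed = 3)
  expect_identical(n1$raw, n2$raw)
})

test_that("generate_study honours protocol durations, skips and seeding", {
  cfg <- study_config(n_subjects = 11, seed = 5)
  study <- generate_study(cfg)
  # 9 full subjects x 6 + two kids x 2
  expect_length(study$recordings, 9 * 6 + 2 * 2)
  pats10 <- vapply(Filter(function(r) r$subject == 10, study$recordings),
                   `[[`, character(1), "pattern")
  pats11 <- vapply(Filter(function(r) r$subject == 11, study$recordings),
                   `[[`, character(1), "pattern")
  expect_setequal(pats10, c("normal", "tachypnea"))
  expect_setequal(pats11, c("normal", "bradapnea"))
  # a 2-min recording carries 6000 nominal-rate samples' worth of signal
  rec1 <- study$recordings[[1]]
  expect_equal(rec1$waveform$duration_s * 50, 6000)
  expect_equal(nrow(rec1$recording$samples), round(120 * 52.5))
  # determinism
  study2 <- generate_study(study_config(n_subjects = 11, seed = 5))
  expect_identical(study$recordings[[13]]$recording$samples,
                   study2$recordings[[13]]$recording$samples)
  expect_error(study_config(skip = list("1" = "limp")), "unknown pattern")
})
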