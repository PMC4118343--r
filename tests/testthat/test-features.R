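test_that("window segmentation reproduces the protocol trial counts", {
  expect_length(segment_windows(120 * 50, 50), 60L)   # 2-min class
  expect_length(segment_windows(60 * 50, 50), 30L)    # 1-min class
  w <- segment_windows(10 * 50, 50)
  expect_length(w, 5L)
  expect_equal(vapply(w, function(x) length(x$idx), integer(1)),
               c(500L, 400L, 300L, 200L, 100L))       # 4 truncated tails
  expect_equal(vapply(w, `[[`, numeric(1), "start_s"), c(0, 2, 4, 6, 8))
  expect_error(segment_windows(0, 50), "empty")
})

test_that("derived channels match their definitions", {
  win <- rbind(c(3, 4, 0), c(3, 4, 0), c(0, 0, 5))
  ch <- derive_channels(win, quiet = TRUE)
  expect_equal(ch$Mag, c(5, 5, 5))
  expect_equal(ch$z_d, win[, 3] - mean(win[, 3]))
  # z-score uses the sample SD (n - 1)
  ch2 <- derive_channels(cbind(1:3, 1:3, 1:3), quiet = TRUE)
  expect_equal(ch2$x_N, (1:3 - 2) / 1)
  # constant channel -> _d zero, _N zero with a message
  expect_message(ch3 <- derive_channels(cbind(rep(2, 4), 1:4, 1:4)),
                 "zero-variance")
  expect_equal(ch3$x_d, rep(0, 4))
  expect_equal(ch3$x_N, rep(0, 4))
})

test_that("basic features implement the printed formulas", {
  expect_equal(basic_feature("Mean", 1:3), 2)
  expect_equal(basic_feature("Energy", 1:3), 14)
  expect_equal(basic_feature("Max", c(1, 7, 2)), 7)
  # population (1/n) standard deviation
  expect_equal(basic_feature("SD", 1:3), sqrt(2 / 3))
  s <- sin(1:50)
  expect_equal(basic_feature("Corr", s, s), 1)
  expect_equal(basic_feature("Corr", s, -s), -1)
  expect_error(basic_feature("Corr", s, rep(1, 50)), "zero-variance")
  expect_error(basic_feature("P", s), "rate_hz")
  # P counts gated maxima: 0.25 Hz sine over 60 s -> 15
  t <- seq(0, 60 - 1 / 50, by = 1 / 50)
  expect_equal(basic_feature("P", sin(2 * pi * 0.25 * t), rate_hz = 50), 15)
})

test_that("feature scale/shift covariance follows the formulas", {
  s <- breathclass:::with_seed(5, rnorm(100))
  a <- 2.5; b <- 1.3
  expect_equal(basic_feature("Energy", a * s),
               a^2 * basic_feature("Energy", s))
  expect_equal(basic_feature("SD", a * s), abs(a) * basic_feature("SD", s))
  expect_equal(basic_feature("Mean", s + b), basic_feature("Mean", s) + b)
  expect_equal(basic_feature("Max", s + b), basic_feature("Max", s) + b)
})

test_that("ApEn matches hand arithmetic and the brute-force oracle", {
  # alternating 0/1, m = 2: exact closed-form value
  expect_equal(apen(rep(c(0, 1), 5), m = 2, r = 0.15),
               (1 / 9) * (5 * log(5 / 9) + 4 * log(4 / 9)) - log(1 / 2),
               tolerance = 1e-12)
  expect_equal(apen(rep(3.7, 40)), 0)
  expect_error(apen(1:5, m = 5), "too short")
  # brute-force agreement on random short series
  for (seed in 1:5) {
    u <- breathclass:::with_seed(seed, rnorm(40))
    expect_equal(apen(u, m = 2, r = 0.3), oracle_apen(u, 2, 0.3),
                 tolerance = 1e-10)
    expect_equal(apen(u, m = 5, r = 0.15), oracle_apen(u, 5, 0.15),
                 tolerance = 1e-10)
  }
})

test_that("ApEn orders regularity: noise above sinusoid, never negative", {
  n <- 500
  noise <- breathclass:::with_seed(11, rnorm(n))
  sine <- sin(2 * pi * 5 * seq_len(n) / n)
  expect_gt(apen(noise, 2, 0.2 * sd(noise)), apen(sine, 2, 0.2 * sd(sine)))
  for (seed in 1:8) {
    u <- breathclass:::with_seed(seed, cumsum(rnorm(60)))
    expect_gte(apen(u, 2, 0.5), -1e-12)
  }
})

test_that("feature matrix has the full candidate pool per window", {
  pool <- default_feature_pool()
  expect_equal(nrow(pool), 26L)
  spec <- pattern_spec("normal")
  wf <- generate_breath_waveform(spec, 10, 50, seed = 2)
  rec <- project_to_accelerometer(wf, sensor_model(measured_rate_hz = 50),
                                  seed = 3)
  fm <- extract_feature_matrix(rec, label = "normal")
  expect_equal(nrow(fm), 5L)
  expect_true(all(pool$name %in% names(fm)))
  expect_true(all(is.finite(as.matrix(fm[, pool$name]))))
  expect_equal(unique(fm$label), "normal")
  # restricted pool -> single feature column
  fm1 <- extract_feature_matrix(rec, pool = pool[pool$name == "Mean(x)", ])
  expect_named(fm1, c("window", "start_s", "Mean(x)"))
})

test_that("ApEn on the normalized breathing axis separates Biot's from normal", {
  # y is the dominant breathing-coupling axis in the default sensor model,
  # so the regularity contrast (apneic bursts vs continuous breathing)
  # shows there; a two-sample comparison at fixed seed
  mk <- function(p, seed) {
    wf <- generate_breath_waveform(pattern_spec(p), 60, 50, seed = seed)
    rec <- project_to_accelerometer(wf, sensor_model(), seed = seed + 1)
    rec <- preprocess_recording(rec)
    extract_feature_matrix(rec)
  }
  fn <- mk("normal", 21)
  fb <- mk("biots", 22)
  tt <- stats::t.test(fn[["ApEn(y_N)"]], fb[["ApEn(y_N)"]])
  expect_lt(tt$p.value, 0.01)
})
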