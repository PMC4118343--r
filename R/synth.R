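# Synthetic breath-waveform and chest-accelerometer simulator.
#
# Each breath is a raised-cosine full cycle amp * (1 - cos(2*pi*t/T)) / 2:
# smooth, zero at both breath boundaries, and with exactly one local maximum
# at the breath midpoint, so ground-truth peak times are known exactly.

#' Breathing pattern names understood by the simulator
#' @export
breath_patterns <- function() {
  c("normal", "bradapnea", "tachypnea", "cheyne_stokes", "kussmaul", "biots")
}

pattern_defaults <- function(pattern) {
  switch(pattern,
    normal        = list(rate_rpm = 15, amplitude = 1.0),
    bradapnea     = list(rate_rpm = 8,  amplitude = 1.0),
    tachypnea     = list(rate_rpm = 30, amplitude = 0.8),
    # Cheyne-Stokes / Biot's cycles (active phase + apnea) fit inside one
    # 10-s analysis window, as the emulated protocol states
    cheyne_stokes = list(rate_rpm = 45, amplitude = 1.0,
                         envelope_period_s = 6, apnea_s = 4),
    kussmaul      = list(rate_rpm = 28, amplitude = 2.5),
    biots         = list(rate_rpm = 40, amplitude = 1.2,
                         apnea_s = 4, burst_breaths = 4L),
    stopf("unknown breathing pattern '%s'", pattern)
  )
}

#' Specification of one breathing pattern
#'
#' Builds a validated parameter set for the waveform generator. Defaults
#' encode the trial protocol the simulator emulates: tachypnea above 20
#' breaths/min, bradypnea below 12, Cheyne-Stokes with a sinusoidal
#' crescendo-decrescendo envelope followed by apnea, Biot's respiration as
#' constant-amplitude bursts separated by apnea, Kussmaul as fast and deep
#' (large amplitude) breathing. Apnea pauses are at least 3 s.
#'
#' @param pattern one of [breath_patterns()].
#' @param rate_rpm breathing rate in breaths per minute (during active
#'   breathing for the apneic patterns).
#' @param amplitude peak breath amplitude, arbitrary volume-like units.
#' @param apnea_s apnea duration in seconds (Cheyne-Stokes and Biot's only;
#'   must be >= 3 per the emulated protocol).
#' @param envelope_period_s duration of the Cheyne-Stokes active
#'   crescendo-decrescendo phase, seconds.
#' @param burst_breaths breaths per Biot's burst.
#' @param noise_sd standard deviation of additive Gaussian noise, same
#'   units as `amplitude`.
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(pattern, rate_rpm = NULL, amplitude = NULL,
                         apnea_s = NULL, envelope_period_s = NULL,
                         burst_breaths = NULL, noise_sd = 0.02) {
  pattern <- match.arg(pattern, breath_patterns())
  def <- pattern_defaults(pattern)
  spec <- list(
    pattern = pattern,
    rate_rpm = if (is.null(rate_rpm)) def$rate_rpm else rate_rpm,
    amplitude = if (is.null(amplitude)) def$amplitude else amplitude,
    apnea_s = if (is.null(apnea_s)) def$apnea_s else apnea_s,
    envelope_period_s = if (is.null(envelope_period_s)) def$envelope_period_s
                        else envelope_period_s,
    burst_breaths = if (is.null(burst_breaths)) def$burst_breaths
                    else as.integer(burst_breaths),
    noise_sd = noise_sd
  )
  assert_scalar_num(spec$rate_rpm, "rate_rpm", positive = TRUE)
  assert_scalar_num(spec$amplitude, "amplitude", positive = TRUE)
  assert_scalar_num(spec$noise_sd, "noise_sd", nonneg = TRUE)
  if (pattern == "tachypnea" && spec$rate_rpm <= 20)
    stopf("tachypnea requires rate_rpm > 20 breaths/min")
  if (pattern == "bradapnea" && spec$rate_rpm >= 12)
    stopf("bradapnea requires rate_rpm < 12 breaths/min")
  if (pattern %in% c("cheyne_stokes", "biots")) {
    assert_scalar_num(spec$apnea_s, "apnea_s", nonneg = TRUE)
    if (spec$apnea_s < 3)
      stopf("apnea_s must be >= 3 s for %s (protocol floor)", pattern)
  }
  if (pattern == "cheyne_stokes")
    assert_scalar_num(spec$envelope_period_s, "envelope_period_s",
                      positive = TRUE)
  if (pattern == "biots" && spec$burst_breaths < 1L)
    stopf("burst_breaths must be >= 1")
  structure(spec, class = "pattern_spec")
}

# Breath schedule: one row per breath (start time, period, amplitude).
# Apnea is simply the absence of a scheduled breath (waveform = 0).
breath_schedule <- function(spec, duration_s) {
  period <- 60 / spec$rate_rpm
  switch(spec$pattern,
    cheyne_stokes = {
      n_active <- floor(spec$envelope_period_s / period)
      if (n_active < 1L)
        stopf("envelope_period_s too short for one breath at %g rpm",
              spec$rate_rpm)
      cycle <- spec$envelope_period_s + spec$apnea_s
      starts <- c(); amps <- c()
      cyc0 <- 0
      while (cyc0 < duration_s) {
        mids <- (seq_len(n_active) - 0.5) * period
        # per-breath amplitude from the sinusoidal envelope at breath midpoint
        env <- sin(pi * mids / spec$envelope_period_s)
        starts <- c(starts, cyc0 + (seq_len(n_active) - 1) * period)
        amps <- c(amps, spec$amplitude * env)
        cyc0 <- cyc0 + cycle
      }
      keep <- starts < duration_s
      data.frame(start = starts[keep], period = period, amp = amps[keep])
    },
    biots = {
      nb <- spec$burst_breaths
      cycle <- nb * period + spec$apnea_s
      starts <- c()
      cyc0 <- 0
      while (cyc0 < duration_s) {
        starts <- c(starts, cyc0 + (seq_len(nb) - 1) * period)
        cyc0 <- cyc0 + cycle
      }
      starts <- starts[starts < duration_s]
      data.frame(start = starts, period = period, amp = spec$amplitude)
    },
    {
      starts <- seq(0, duration_s, by = period)
      starts <- starts[starts < duration_s]
      data.frame(start = starts, period = period, amp = spec$amplitude)
    }
  )
}

#' Generate a synthetic respiration waveform
#'
#' Returns a volume-like respiration series built from raised-cosine breath
#' cycles, together with the exact peak times of its noiseless component.
#'
#' @param spec a [pattern_spec()].
#' @param duration_s recording duration in seconds (> 0).
#' @param rate_hz sampling rate in Hz (> 0).
#' @param seed integer seed for the additive noise; same `(spec, seed)` gives
#'   an identical series.
#' @return an object of class `breath_waveform` with elements `series`,
#'   `times`, `peak_times`, `rate_hz`, `duration_s`, `spec`.
#' @export
generate_breath_waveform <- function(spec, duration_s, rate_hz, seed = 1L) {
  stopifnot(inherits(spec, "pattern_spec"))
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  sched <- breath_schedule(spec, duration_s)
  w <- numeric(n)
  for (k in seq_len(nrow(sched))) {
    i0 <- which(t >= sched$start[k] & t < sched$start[k] + sched$period[k])
    if (length(i0))
      w[i0] <- w[i0] + sched$amp[k] *
        (1 - cos(2 * pi * (t[i0] - sched$start[k]) / sched$period[k])) / 2
  }
  mids <- sched$start + sched$period / 2
  peak_times <- mids[mids <= t[n]]
  noisy <- w
  if (spec$noise_sd > 0)
    noisy <- w + with_seed(seed, rnorm(n, sd = spec$noise_sd))
  structure(list(series = noisy, clean = w, times = t,
                 peak_times = peak_times, rate_hz = rate_hz,
                 duration_s = duration_s, spec = spec),
            class = "breath_waveform")
}

#' Chest-sensor forward model
#'
#' Describes how a respiration waveform appears in a chest-mounted triaxial
#' accelerometer: a constant gravity projection (DC), a small tilt
#' modulation proportional to the normalized waveform on each axis, additive
#' Gaussian noise, a known gain/offset distortion (the inverse of
#' `true_calibration`, so that calibration fitting is exercised), and a
#' measured sampling rate that differs from the nominal one.
#'
#' @param gravity_axis unit 3-vector of the gravity direction in sensor
#'   coordinates.
#' @param respiratory_axis_mix 3-vector of per-axis coupling gains in g per
#'   unit of normalized waveform (chest breathing tilt is of order 0.01 g).
#' @param true_calibration a [calibration_model()] used to distort the
#'   simulated output.
#' @param nominal_rate_hz rate the sensor claims (Hz).
#' @param measured_rate_hz rate the sensor actually logs at (Hz).
#' @param noise_sd_g per-axis Gaussian noise SD in g.
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(gravity_axis = c(0, 0, 1),
                         respiratory_axis_mix = c(0.005, 0.02, 0.008),
                         true_calibration = calibration_model(),
                         nominal_rate_hz = 50,
                         measured_rate_hz = 52.5,
                         noise_sd_g = 0.002) {
  stopifnot(length(gravity_axis) == 3L, length(respiratory_axis_mix) == 3L)
  if (abs(sqrt(sum(gravity_axis^2)) - 1) > 1e-9)
    stopf("gravity_axis must be a unit vector")
  assert_scalar_num(nominal_rate_hz, "nominal_rate_hz", positive = TRUE)
  assert_scalar_num(measured_rate_hz, "measured_rate_hz", positive = TRUE)
  assert_scalar_num(noise_sd_g, "noise_sd_g", nonneg = TRUE)
  stopifnot(inherits(true_calibration, "calibration_model"))
  structure(list(gravity_axis = as.numeric(gravity_axis),
                 respiratory_axis_mix = as.numeric(respiratory_axis_mix),
                 true_calibration = true_calibration,
                 nominal_rate_hz = nominal_rate_hz,
                 measured_rate_hz = measured_rate_hz,
                 noise_sd_g = noise_sd_g),
            class = "sensor_model")
}

#' Project a respiration waveform into a triaxial accelerometer recording
#'
#' Each axis is gravity DC + coupling gain times the mean-centered waveform
#' (native amplitude units, so breath depth is preserved) plus Gaussian
#' noise; the result is then distorted by the inverse of the sensor's true
#' calibration and sampled at the measured (not nominal) rate.
#'
#' @param waveform a [generate_breath_waveform()] result.
#' @param sensor a [sensor_model()].
#' @param seed integer noise seed.
#' @return a [triaxial_recording()] labelled with both rates.
#' @export
project_to_accelerometer <- function(waveform, sensor = sensor_model(),
                                     seed = 1L) {
  stopifnot(inherits(waveform, "breath_waveform"),
            inherits(sensor, "sensor_model"))
  if (!length(waveform$series)) stopf("waveform is empty")
  G <- sensor$true_calibration$params[1:3, , drop = FALSE]
  if (abs(det(G)) <= 1e-12)
    stopf("singular gain block in true_calibration")
  dur <- waveform$duration_s
  m <- round(dur * sensor$measured_rate_hz)
  tm <- (seq_len(m) - 1) / sensor$measured_rate_hz
  wm <- approx(waveform$times, waveform$series, xout = tm, rule = 2)$y
  # mean-centered, native amplitude units: coupling gains are g per unit of
  # breath amplitude, so deep breathing (e.g. Kussmaul) tilts the chest more
  wN <- wm - mean(wm)
  ideal <- outer(rep(1, m), sensor$gravity_axis) +
    outer(wN, sensor$respiratory_axis_mix)
  if (sensor$noise_sd_g > 0)
    ideal <- ideal + with_seed(seed,
      matrix(rnorm(3 * m, sd = sensor$noise_sd_g), ncol = 3))
  offset <- sensor$true_calibration$params[4, ]
  raw <- sweep(ideal, 2, offset) %*% solve(G)
  triaxial_recording(times = tm, samples = raw,
                     nominal_rate_hz = sensor$nominal_rate_hz,
                     measured_rate_hz = sensor$measured_rate_hz)
}

#' Simulate a six-position stationary calibration batch
#'
#' Emulates the standard calibration procedure in which the sensor is held
#' still in six orientations so that the known input is a unit gravity
#' vector along plus/minus each axis. Raw readings are the inverse-calibrated
#' gravity vectors plus seeded Gaussian noise.
#'
#' @param true_model the [calibration_model()] that generated the distortion.
#' @param noise_sd_g Gaussian noise SD in g.
#' @param seed integer seed.
#' @return a [stationary_batch()].
#' @export
generate_stationary_batch <- function(true_model = calibration_model(),
                                      noise_sd_g = 0, seed = 1L) {
  stopifnot(inherits(true_model, "calibration_model"))
  assert_scalar_num(noise_sd_g, "noise_sd_g", nonneg = TRUE)
  gravity <- rbind(diag(3), -diag(3))
  G <- true_model$params[1:3, , drop = FALSE]
  offset <- true_model$params[4, ]
  raw <- sweep(gravity, 2, offset) %*% solve(G)
  if (noise_sd_g > 0)
    raw <- raw + with_seed(seed,
      matrix(rnorm(length(raw), sd = noise_sd_g), ncol = 3))
  stationary_batch(raw = raw, gravity = gravity)
}

#' Study (trial-protocol) configuration for the simulator
#'
#' The defaults state the emulated protocol: 11 subjects; 2-minute
#' recordings of normal, bradypnea, tachypnea and Cheyne-Stokes breathing
#' and 1-minute recordings of Kussmaul and Biot's breathing; nominal 50 Hz
#' sampling logged at a measured ~52.5 Hz; two child subjects (ids 10 and
#' 11) who performed only two patterns each. Subject ages default to the
#' emulated cohort (mean 26.54, sample SD 11.9026 years).
#'
#' @param n_subjects number of subjects to simulate.
#' @param durations_s named per-pattern durations in seconds.
#' @param skip named list: subject id (as character) -> patterns not
#'   performed by that subject.
#' @param ages numeric vector of subject ages (recycled/truncated to
#'   `n_subjects`).
#' @param sensor base [sensor_model()] for all subjects.
#' @param seed master integer seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_subjects = 11L,
                         durations_s = c(normal = 120, bradapnea = 120,
                                         tachypnea = 120, cheyne_stokes = 120,
                                         kussmaul = 60, biots = 60),
                         skip = list(
                           "10" = c("bradapnea", "cheyne_stokes",
                                    "kussmaul", "biots"),
                           "11" = c("tachypnea", "cheyne_stokes",
                                    "kussmaul", "biots")),
                         ages = c(48, 37, 30, 29, 28, 28, 28, 27, 24, 9, 4),
                         sensor = sensor_model(),
                         seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (!all(breath_patterns() %in% names(durations_s)))
    stopf("durations_s must name all six patterns")
  bad <- setdiff(unlist(skip), breath_patterns())
  if (length(bad)) stopf("unknown pattern in skip table: %s", bad[1])
  structure(list(n_subjects = n_subjects, durations_s = durations_s,
                 skip = skip, ages = rep_len(ages, n_subjects),
                 sensor = sensor, seed = as.integer(seed)),
            class = "study_config")
}

# Per-subject pattern parameter draws: distinct rate/amplitude ranges keep
# the six classes geometrically distinct in feature space while varying
# across subjects.
draw_pattern_spec <- function(pattern, seed) {
  with_seed(seed, {
    switch(pattern,
      normal        = pattern_spec("normal", rate_rpm = runif(1, 13, 18)),
      bradapnea     = pattern_spec("bradapnea", rate_rpm = runif(1, 6, 10)),
      tachypnea     = pattern_spec("tachypnea", rate_rpm = runif(1, 25, 35)),
      cheyne_stokes = pattern_spec("cheyne_stokes",
                                   rate_rpm = runif(1, 38, 52),
                                   apnea_s = runif(1, 3, 5)),
      kussmaul      = pattern_spec("kussmaul", rate_rpm = runif(1, 24, 32),
                                   amplitude = runif(1, 2.2, 2.8)),
      biots         = pattern_spec("biots", rate_rpm = runif(1, 34, 46),
                                   apnea_s = runif(1, 3, 5),
                                   burst_breaths = sample(3:5, 1))
    )
  })
}

subject_patterns <- function(config, subject) {
  skip <- config$skip[[as.character(subject)]]
  setdiff(breath_patterns(), skip)
}

#' Generate a full labelled synthetic study
#'
#' Simulates every subject/pattern recording of the emulated protocol,
#' honouring the per-subject skip table, with a deterministic seed
#' hierarchy: the same configuration always reproduces the identical study.
#'
#' @param config a [study_config()].
#' @return an object of class `breath_study`: a list with `config` and
#'   `recordings`, the latter a list of entries holding `subject`,
#'   `pattern`, `spec`, `waveform` (ground truth) and `recording`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  out <- list()
  for (s in seq_len(config$n_subjects)) {
    pats <- subject_patterns(config, s)
    for (p in pats) {
      pseed <- derive_seed(config$seed, s, match(p, breath_patterns()))
      spec <- draw_pattern_spec(p, pseed)
      dur <- config$durations_s[[p]]
      wf <- generate_breath_waveform(spec, dur,
                                     config$sensor$nominal_rate_hz,
                                     seed = pseed + 1L)
      sens <- config$sensor
      # mild per-subject coupling variation
      sens$respiratory_axis_mix <- sens$respiratory_axis_mix *
        with_seed(derive_seed(config$seed, s), runif(1, 0.8, 1.2))
      rec <- project_to_accelerometer(wf, sens, seed = pseed + 2L)
      out[[length(out) + 1L]] <- list(subject = s, pattern = p, spec = spec,
                                      waveform = wf, recording = rec)
    }
  }
  structure(list(config = config, recordings = out), class = "breath_study")
}

#' @export
print.breath_study <- function(x, ...) {
  cat(sprintf("<breath_study> %d subjects, %d recordings\n",
              x$config$n_subjects, length(x$recordings)))
  invisible(x)
}
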