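# Pipeline configuration and the end-to-end runner.

#' Pipeline configuration with protocol defaults
#'
#' All tunable parameters of the pipeline, with the defaults of the
#' emulated protocol: order-10 Butterworth at 1 Hz, spirometer smoothing
#' window 30, 10 s / 2 s analysis windows, ApEn m = 5 and r = 0.15, RBF
#' sigma = 1, 70/30 train/test split.
#'
#' @param ... overrides of the default fields.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter_order = 10L, cutoff_hz = 1, smooth_window = 30L,
    nominal_rate_hz = 50, rate_window_s = 60,
    min_peak_distance_s = 0.4, min_prominence_frac = 0.1,
    window_length_s = 10, window_shift_s = 2,
    apen_m = 5L, apen_r = 0.15,
    kernel = "rbf", sigma = 1, svm_C = 1e3,
    train_frac = 0.7, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field '%s'", unknown[1])
  cfg <- modifyList(cfg, over)
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stopf("train_frac must be in (0, 1)")
  assert_scalar_num(cfg$cutoff_hz, "cutoff_hz", positive = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of config fields.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

cfg_kernel <- function(cfg) kernel_spec(cfg$kernel, sigma = cfg$sigma)

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the respiration-rate pipeline on one recording
#'
#' Stage order: read, calibrate (optional), zero-phase lowpass, measured
#' sampling-rate estimation, rational resampling to the nominal rate,
#' cross-correlation synchronization against an optional smoothed reference
#' channel, then respiration-rate estimation on the dominant breathing
#' axis. Every stage logs its parameters to stderr; a failing stage aborts
#' with its name.
#'
#' @param config a [pipeline_config()].
#' @param recording_path CSV recording path (or a `triaxial_recording`).
#' @param calibration_path optional calibration-model JSON.
#' @param reference_path optional reference waveform CSV (`time_s,value`).
#' @return report list with the measured rate, sync lag (if a reference was
#'   given), chosen axis and the [respiration_rate()] estimate.
#' @export
run_pipeline <- function(config = pipeline_config(), recording_path,
                         calibration_path = NULL, reference_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  rec <- run_stage("read", {
    r <- if (inherits(recording_path, "triaxial_recording")) recording_path
         else read_recording(recording_path, config$nominal_rate_hz)
    log_stage("read", "%d samples at nominal %g Hz", nrow(r$samples),
              r$nominal_rate_hz)
    r
  })
  if (!is.null(calibration_path)) {
    rec <- run_stage("calibrate", {
      model <- if (inherits(calibration_path, "calibration_model"))
        calibration_path else read_calibration_json(calibration_path)
      log_stage("calibrate", "applying 12-parameter model")
      apply_calibration(rec, model)
    })
  }
  measured <- run_stage("measured-rate", {
    m <- if (!is.null(rec$measured_rate_hz)) rec$measured_rate_hz
         else estimate_measured_rate(rec)
    log_stage("measured-rate", "%.4g Hz (lead %.4g s/s)", m,
              sampling_time_lead(rec$nominal_rate_hz, m))
    m
  })
  rec$measured_rate_hz <- measured
  clean <- run_stage("filter+resample", {
    r <- preprocess_recording(rec, cutoff_hz = config$cutoff_hz,
                              order = config$filter_order)
    log_stage("filter+resample",
              "order-%d lowpass at %g Hz; %d samples at %g Hz",
              config$filter_order, config$cutoff_hz, nrow(r$samples),
              r$nominal_rate_hz)
    r
  })
  axis <- run_stage("axis", {
    a <- breathing_axis(clean)
    log_stage("axis", "breathing axis = %s", c("x", "y", "z")[a])
    a
  })
  signal <- clean$samples[, axis]
  lag <- NULL
  if (!is.null(reference_path)) {
    lag <- run_stage("synchronize", {
      ref <- read_waveform(reference_path)
      sm <- moving_smooth(ref$series, config$smooth_window)
      n <- min(length(sm), length(signal))
      l <- cross_correlation_lag(signal[seq_len(n)], sm[seq_len(n)],
                                 max_lag = min(n - 1L,
                                   as.integer(5 * clean$nominal_rate_hz)))
      log_stage("synchronize", "lag %d samples", l)
      l
    })
  }
  est <- run_stage("rate", {
    w <- min(config$rate_window_s, length(signal) / clean$nominal_rate_hz)
    e <- respiration_rate(signal, clean$nominal_rate_hz, window_s = w,
                          min_peak_distance_s = config$min_peak_distance_s,
                          min_prominence_frac = config$min_prominence_frac)
    log_stage("rate", "%.2f breaths/min", e$rpm)
    e
  })
  list(measured_rate_hz = measured,
       time_lead_s_per_s = sampling_time_lead(rec$nominal_rate_hz, measured),
       axis = c("x", "y", "z")[axis], sync_lag = lag, rate = est,
       config = config)
}
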