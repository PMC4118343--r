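# Windowed feature extraction over raw, DC-removed, normalized and
# magnitude channels, including Approximate Entropy.

#' Analysis-window specification
#'
#' @param length_s window length in seconds (default 10 s, long enough to
#'   contain at least one full breathing cycle including an apnea pause).
#' @param shift_s shift between consecutive windows (default 2 s).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length_s = 10, shift_s = 2) {
  assert_scalar_num(length_s, "length_s", positive = TRUE)
  assert_scalar_num(shift_s, "shift_s", positive = TRUE)
  if (shift_s > length_s) stopf("shift_s must not exceed length_s")
  structure(list(length_s = length_s, shift_s = shift_s),
            class = "window_spec")
}

#' Segment a series into overlapping windows
#'
#' One window per shift increment over the whole duration:
#' `floor(duration / shift)` windows, with trailing windows truncated to the
#' available samples. A 120-s recording at the 10 s / 2 s default yields 60
#' windows, a 60-s recording 30 — the bookkeeping that makes per-class
#' trial counts (42 training / 18 test windows for a 2-min class at a 70/30
#' split) come out exactly.
#'
#' @param n number of samples.
#' @param rate_hz sampling rate (Hz).
#' @param spec a [window_spec()].
#' @return list of windows, each `list(start_s, idx)`.
#' @export
segment_windows <- function(n, rate_hz, spec = window_spec()) {
  n <- as.integer(n)
  if (n < 1L) stopf("empty series")
  assert_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  duration <- n / rate_hz
  n_win <- floor(duration / spec$shift_s + 1e-9)
  lapply(seq_len(n_win) - 1L, function(k) {
    start <- k * spec$shift_s
    i0 <- floor(start * rate_hz) + 1L
    i1 <- min(n, ceiling((start + spec$length_s) * rate_hz))
    list(start_s = start, idx = seq(i0, i1))
  })
}

#' Derive analysis channels from a 3-axis window
#'
#' Produces the raw axes, the per-sample magnitude
#' `Mag = sqrt(x^2 + y^2 + z^2)`, the DC-removed channels (`x_d`, ...) and
#' the z-score normalized channels (`x_N`, ..., sample SD). A zero-variance
#' channel normalizes to all zeros with a message.
#'
#' @param window n x 3 matrix (columns x, y, z).
#' @param quiet suppress the zero-variance message.
#' @return named list of numeric channels.
#' @export
derive_channels <- function(window, quiet = FALSE) {
  window <- as.matrix(window)
  if (!nrow(window) || ncol(window) != 3L)
    stopf("window must be a non-empty n x 3 matrix")
  ch <- list(x = window[, 1], y = window[, 2], z = window[, 3])
  ch$Mag <- sqrt(ch$x^2 + ch$y^2 + ch$z^2)
  for (a in c("x", "y", "z")) {
    v <- ch[[a]]
    ch[[paste0(a, "_d")]] <- v - mean(v)
    s <- sd(v)
    if (s > 0) {
      ch[[paste0(a, "_N")]] <- (v - mean(v)) / s
    } else {
      if (!quiet) message("zero-variance channel ", a,
                          ": normalized to zeros")
      ch[[paste0(a, "_N")]] <- rep(0, length(v))
    }
  }
  ch
}

#' Basic window statistics
#'
#' The classic windowed statistics used for breathing-pattern recognition:
#' `Mean`, `SD` (population, 1/n normalization), `Max`, `Energy` (sum of
#' squares), `Corr` (Pearson inter-axis correlation) and `P` (count of gated
#' local maxima, sharing the peak gates of [respiration_rate()]).
#'
#' @param name one of "Mean", "SD", "Corr", "Energy", "Max", "P".
#' @param s numeric channel.
#' @param s2 second channel (Corr only).
#' @param rate_hz sampling rate, needed by `P` for its distance gate.
#' @param min_peak_distance_s,min_prominence_frac peak gates for `P`.
#' @return scalar feature value.
#' @export
basic_feature <- function(name, s, s2 = NULL, rate_hz = NULL,
                          min_peak_distance_s = 0.4,
                          min_prominence_frac = 0.1) {
  if (!length(s)) stopf("empty channel")
  switch(name,
    Mean = mean(s),
    Max = max(s),
    Energy = sum(s^2),
    SD = sqrt(mean((s - mean(s))^2)),
    Corr = {
      if (is.null(s2) || length(s2) != length(s))
        stopf("Corr needs two channels of equal length")
      if (sd(s) == 0 || sd(s2) == 0)
        stopf("undefined correlation: zero-variance input")
      cor(s, s2)
    },
    P = {
      if (is.null(rate_hz)) stopf("P needs rate_hz for its distance gate")
      rng <- diff(range(s))
      if (rng == 0) 0 else
        length(find_peaks(s,
          min_distance = max(1L, round(min_peak_distance_s * rate_hz)),
          min_prominence = min_prominence_frac * rng))
    },
    stopf("unknown feature '%s'", name)
  )
}

#' Approximate Entropy
#'
#' Regularity statistic of Pincus: with template length `m` and tolerance
#' `r`, ApEn = phi_m - phi_{m+1} where
#' phi_m = (n-m+1)^-1 sum_i log C_i^m and C_i^m is the fraction of template
#' vectors (self-match included) within Chebyshev distance `r` of template
#' i. Low values indicate a regular signal (exactly 0 for a constant);
#' irregular signals score higher. Defaults `m = 5`, `r = 0.15` are tuned
#' for z-normalized 10-s accelerometer windows, where an absolute tolerance
#' of 0.15 equals 0.15 raw-signal standard deviations.
#'
#' @param u numeric series (length >= m + 2).
#' @param m template length.
#' @param r tolerance, in units of `u`.
#' @return scalar ApEn value (>= 0 up to numerical noise).
#' @export
apen <- function(u, m = 5L, r = 0.15) {
  u <- as.numeric(u)
  n <- length(u)
  m <- as.integer(m)
  if (m < 1L) stopf("m must be >= 1")
  assert_scalar_num(r, "r", positive = TRUE)
  if (n < m + 2L)
    stopf("series of length %d too short for ApEn with m = %d", n, m)
  W <- abs(outer(u, u, "-")) <= r
  phi <- function(mm) {
    N <- n - mm + 1L
    M <- W[seq_len(N), seq_len(N), drop = FALSE]
    if (mm > 1L) for (k in seq_len(mm - 1L))
      M <- M & W[seq_len(N) + k, seq_len(N) + k, drop = FALSE]
    mean(log(rowSums(M) / N))
  }
  phi(m) - phi(m + 1L)
}

#' Default candidate feature pool
#'
#' The pool the per-branch selection searches: Mean/SD/Max/P on each axis
#' and the magnitude, Energy on the DC-removed channels and the magnitude,
#' ApEn on the normalized channels, and the three inter-axis correlations.
#'
#' @return data.frame with columns `name`, `feature`, `channel`, `channel2`.
#' @export
default_feature_pool <- function() {
  rows <- list()
  add <- function(feature, channel, channel2 = NA_character_) {
    nm <- if (feature == "Corr")
      sprintf("Corr(%s,%s)", channel, channel2)
    else sprintf("%s(%s)", if (feature == "Energy") "E" else feature, channel)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = nm, feature = feature, channel = channel, channel2 = channel2,
      stringsAsFactors = FALSE)
  }
  for (f in c("Mean", "SD", "Max", "P"))
    for (c in c("x", "y", "z", "Mag")) add(f, c)
  for (c in c("x_d", "y_d", "z_d", "Mag")) add("Energy", c)
  for (c in c("x_N", "y_N", "z_N")) add("ApEn", c)
  add("Corr", "x", "y"); add("Corr", "x", "z"); add("Corr", "y", "z")
  do.call(rbind, rows)
}

compute_pool_features <- function(channels, pool, rate_hz,
                                  apen_m = 5L, apen_r = 0.15) {
  out <- numeric(nrow(pool))
  names(out) <- pool$name
  for (i in seq_len(nrow(pool))) {
    f <- pool$feature[i]
    s <- channels[[pool$channel[i]]]
    out[i] <- switch(f,
      ApEn = apen(s, m = apen_m, r = apen_r),
      Corr = basic_feature("Corr", s, channels[[pool$channel2[i]]]),
      basic_feature(f, s, rate_hz = rate_hz))
  }
  out
}

#' Extract the windowed feature matrix of a recording
#'
#' Segments the recording, derives the analysis channels per window and
#' evaluates every candidate feature, yielding one row per window. Windows
#' in which a feature fails (e.g. an undefined correlation) are dropped with
#' a message reporting the count.
#'
#' @param recording a [triaxial_recording()] (ideally calibrated, filtered
#'   and resampled to its nominal rate).
#' @param window a [window_spec()].
#' @param pool candidate pool as from [default_feature_pool()].
#' @param label optional class label attached to every row.
#' @param apen_m,apen_r Approximate Entropy parameters.
#' @return data.frame: `window`, `start_s`, one column per pool feature,
#'   and `label` if given.
#' @export
extract_feature_matrix <- function(recording, window = window_spec(),
                                   pool = default_feature_pool(),
                                   label = NULL, apen_m = 5L, apen_r = 0.15) {
  stopifnot(inherits(recording, "triaxial_recording"))
  fs <- recording$nominal_rate_hz
  wins <- segment_windows(nrow(recording$samples), fs, window)
  rows <- vector("list", length(wins))
  failed <- 0L
  for (k in seq_along(wins)) {
    rows[[k]] <- tryCatch({
      ch <- derive_channels(recording$samples[wins[[k]]$idx, , drop = FALSE],
                            quiet = TRUE)
      vals <- compute_pool_features(ch, pool, fs, apen_m, apen_r)
      if (!all(is.finite(vals))) stop("non-finite feature")
      c(window = k, start_s = wins[[k]]$start_s, vals)
    }, error = function(e) NULL)
    if (is.null(rows[[k]])) failed <- failed + 1L
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (failed > 0L) message(failed, " window(s) dropped during extraction")
  if (!length(rows)) stopf("no usable windows")
  df <- as.data.frame(do.call(rbind, rows))
  if (!is.null(label)) df$label <- label
  df
}

#' Extract features for every recording of a synthetic study
#'
#' Optionally preprocesses each recording (calibration, zero-phase lowpass
#' filtering and resampling from the measured to the nominal rate) before
#' windowed extraction, and tags rows with subject and pattern label.
#'
#' @param study a [generate_study()] result.
#' @param calibration optional [calibration_model()] applied first.
#' @param preprocess logical: filter and resample to the nominal rate.
#' @param window,pool,apen_m,apen_r see [extract_feature_matrix()].
#' @param cutoff_hz,order lowpass settings.
#' @return data.frame with `subject`, `label` and feature columns.
#' @export
study_feature_table <- function(study, calibration = NULL, preprocess = TRUE,
                                window = window_spec(),
                                pool = default_feature_pool(),
                                apen_m = 5L, apen_r = 0.15,
                                cutoff_hz = 1, order = 10L) {
  stopifnot(inherits(study, "breath_study"))
  tabs <- lapply(study$recordings, function(entry) {
    rec <- entry$recording
    if (!is.null(calibration)) rec <- apply_calibration(rec, calibration)
    if (preprocess) rec <- preprocess_recording(rec, cutoff_hz = cutoff_hz,
                                                order = order)
    df <- extract_feature_matrix(rec, window = window, pool = pool,
                                 label = entry$pattern,
                                 apen_m = apen_m, apen_r = apen_r)
    df$subject <- entry$subject
    df
  })
  do.call(rbind, tabs)
}

#' Filter and resample a recording to its nominal rate
#'
#' Applies the zero-phase Butterworth lowpass per axis, then rational
#' resampling from the measured rate (estimated from timestamps when not
#' already set) down/up to the nominal rate, removing the cumulative
#' sampling-lag error.
#'
#' @param recording a [triaxial_recording()].
#' @param cutoff_hz,order lowpass settings.
#' @param resample logical.
#' @return a [triaxial_recording()] at the nominal rate.
#' @export
preprocess_recording <- function(recording, cutoff_hz = 1, order = 10L,
                                 resample = TRUE) {
  stopifnot(inherits(recording, "triaxial_recording"))
  fs <- recording$measured_rate_hz
  if (is.null(fs)) fs <- tryCatch(estimate_measured_rate(recording),
                                  error = function(e) recording$nominal_rate_hz)
  filt <- apply(recording$samples, 2, lowpass_butterworth, rate_hz = fs,
                order = order, cutoff_hz = cutoff_hz)
  if (resample && abs(fs - recording$nominal_rate_hz) > 1e-9) {
    filt <- apply(filt, 2, rational_resample, from_hz = fs,
                  to_hz = recording$nominal_rate_hz)
    fs_out <- recording$nominal_rate_hz
  } else fs_out <- fs
  n <- nrow(filt)
  triaxial_recording(times = (seq_len(n) - 1) / fs_out, samples = filt,
                     nominal_rate_hz = recording$nominal_rate_hz,
                     measured_rate_hz = if (fs_out == recording$nominal_rate_hz)
                       recording$nominal_rate_hz else fs)
}
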