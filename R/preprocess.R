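# Preprocessing: filtering, smoothing, measured-rate estimation, rational
# resampling, synchronization and respiration-rate computation.

#' Triaxial accelerometer recording
#'
#' @param times strictly increasing sample times in seconds.
#' @param samples n x 3 matrix of accelerations in g (columns x, y, z).
#' @param nominal_rate_hz the rate the sensor was configured to.
#' @param measured_rate_hz the empirically observed rate, or `NULL` if not
#'   yet estimated.
#' @return object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(times, samples, nominal_rate_hz,
                               measured_rate_hz = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stopf("samples must have 3 columns")
  n <- nrow(samples)
  if (n < 1L || length(times) != n) stopf("times/samples length mismatch")
  if (n > 1L && any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  assert_scalar_num(nominal_rate_hz, "nominal_rate_hz", positive = TRUE)
  if (!is.null(measured_rate_hz))
    assert_scalar_num(measured_rate_hz, "measured_rate_hz", positive = TRUE)
  colnames(samples) <- c("x", "y", "z")
  structure(list(times = as.numeric(times), samples = samples,
                 nominal_rate_hz = nominal_rate_hz,
                 measured_rate_hz = measured_rate_hz),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf(
    "<triaxial_recording> %d samples, %.1f s, nominal %.3g Hz%s\n",
    nrow(x$samples), diff(range(x$times)), x$nominal_rate_hz,
    if (is.null(x$measured_rate_hz)) ""
    else sprintf(", measured %.4g Hz", x$measured_rate_hz)))
  invisible(x)
}

rec_duration <- function(rec) nrow(rec$samples) /
  (if (is.null(rec$measured_rate_hz)) rec$nominal_rate_hz
   else rec$measured_rate_hz)

#' Zero-phase Butterworth lowpass filter
#'
#' Order-10, 1 Hz default, matching the respiration band of a chest
#' accelerometer. Applied forward and backward (zero phase) so that
#' cross-correlation synchronization downstream sees no filter-induced lag.
#'
#' @param signal numeric series.
#' @param rate_hz sampling rate in Hz.
#' @param order filter order.
#' @param cutoff_hz -3 dB cutoff in Hz (per pass).
#' @return filtered series, same length.
#' @export
lowpass_butterworth <- function(signal, rate_hz, order = 10L, cutoff_hz = 1) {
  assert_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  if (rate_hz <= 2 * cutoff_hz) stopf("rate_hz must exceed 2 * cutoff_hz")
  if (length(signal) <= 3L * order)
    stopf("signal too short (%d samples) for stable order-%d filtering",
          length(signal), order)
  sos <- butter_lowpass_sos(order, cutoff_hz, rate_hz)
  sos_filtfilt(as.numeric(signal), sos,
               pad = min(length(signal) - 1L,
                         as.integer(ceiling(12 * rate_hz / cutoff_hz))))
}

#' Centered moving-average smoothing
#'
#' Window-30 by default (the convention used for spirometer reference
#' traces). Edges use shrinking windows so the output has the same length.
#'
#' @param signal numeric series.
#' @param window window size in samples.
#' @return smoothed series.
#' @export
moving_smooth <- function(signal, window = 30L) {
  n <- length(signal)
  window <- as.integer(window)
  if (window < 1L) stopf("window must be >= 1")
  if (window > n) stopf("window (%d) exceeds signal length (%d)", window, n)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- cumsum(c(0, signal))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the measured sampling rate of a recording
#'
#' Counts samples in consecutive windows of true time and averages the
#' per-window rate over all complete windows, which is how a logger's real
#' rate (e.g. ~52.5 Hz against a nominal 50 Hz) is discovered.
#'
#' @param recording a [triaxial_recording()].
#' @param window_s analysis-window length in seconds.
#' @return estimated rate in Hz.
#' @export
estimate_measured_rate <- function(recording, window_s = 10) {
  stopifnot(inherits(recording, "triaxial_recording"))
  assert_scalar_num(window_s, "window_s", positive = TRUE)
  tt <- recording$times - recording$times[1]
  n <- length(tt)
  # span counts whole sample intervals: n samples cover n * dt seconds
  span <- if (n > 1L) tt[n] + tt[n] / (n - 1L) else 0
  n_win <- floor(span / window_s + 1e-9)
  if (n_win < 1L)
    stopf("recording spans %.3g s < window of %.3g s", span, window_s)
  counts <- vapply(seq_len(n_win), function(k) {
    sum(tt >= (k - 1) * window_s & tt < k * window_s)
  }, numeric(1))
  mean(counts) / window_s
}

#' Per-second time lead of a nominal vs measured sampling rate
#'
#' A sensor logging at `measured_hz` while its samples are interpreted at
#' `nominal_hz` accumulates a lead of `measured_hz / nominal_hz - 1` seconds
#' per second (0.05 s/s for 52.5 Hz against 50 Hz), the cumulative error
#' that resampling removes.
#'
#' @param nominal_hz nominal rate in Hz.
#' @param measured_hz measured rate in Hz.
#' @return lead in seconds per second.
#' @export
sampling_time_lead <- function(nominal_hz, measured_hz) {
  assert_scalar_num(nominal_hz, "nominal_hz", positive = TRUE)
  assert_scalar_num(measured_hz, "measured_hz", positive = TRUE)
  measured_hz / nominal_hz - 1
}

#' Rational-fraction anti-aliased resampling
#'
#' Approximates `from_hz / to_hz` by p/q via continued fractions
#' (denominator <= `max_den`), upsamples by q, applies a windowed-sinc
#' anti-aliasing FIR and decimates by p. Output length is `ceiling(n q / p)`.
#'
#' @param signal numeric series.
#' @param from_hz input rate (Hz).
#' @param to_hz output rate (Hz).
#' @param max_den largest denominator for the rational approximation.
#' @return resampled series.
#' @export
rational_resample <- function(signal, from_hz, to_hz, max_den = 1000L) {
  assert_scalar_num(from_hz, "from_hz", positive = TRUE)
  assert_scalar_num(to_hz, "to_hz", positive = TRUE)
  x <- as.numeric(signal)
  n <- length(x)
  pq <- best_rational(from_hz / to_hz, max_den)
  p <- pq[["p"]]; q <- pq[["q"]]
  if (p == q) return(x)
  # symmetric edge extension to limit FIR edge roll-off
  half <- 10L * max(p, q)
  ext <- min(n - 1L, as.integer(ceiling(half / q)) + 2L)
  xe <- c(x[seq(ext + 1L, 2L)], x, x[seq(n - 1L, n - ext)])
  up <- numeric(length(xe) * q)
  up[seq(1L, length(up), by = q)] <- xe
  h <- fir_lowpass(cutoff = 1 / max(p, q), half = half) * q
  y <- conv_full(up, h)
  # sample k of the output sits at upsampled index ext*q + 1 + k*p (0-based k)
  m <- ceiling(n * q / p)
  idx <- half + ext * q + 1L + (seq_len(m) - 1L) * p
  y[idx]
}

#' Synchronization lag by normalized cross-correlation
#'
#' Returns the integer lag (in samples) maximizing the Pearson correlation
#' between `a[t]` and `b[t + lag]` over `[-max_lag, max_lag]`; positive lag
#' means `b` is delayed relative to `a`. Ties break toward the smallest
#' absolute lag.
#'
#' @param a,b numeric series.
#' @param max_lag maximum absolute lag to scan, in samples.
#' @return integer lag.
#' @export
cross_correlation_lag <- function(a, b, max_lag) {
  a <- as.numeric(a); b <- as.numeric(b)
  max_lag <- as.integer(max_lag)
  if (length(a) <= max_lag || length(b) <= max_lag)
    stopf("series must be longer than max_lag")
  if (sd(a) == 0 || sd(b) == 0)
    stopf("undefined correlation: zero-variance input")
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(a), length(b) - l)
      cor(a[seq_len(n)], b[seq_len(n) + l])
    } else {
      n <- min(length(b), length(a) + l)
      cor(a[seq_len(n) - l], b[seq_len(n)])
    }
  }, numeric(1))
  cc[is.na(cc)] <- -Inf
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  cand[which.min(abs(cand))]
}

# Strict local maxima with plateau handling (center of flat tops), plus
# standard topographic prominence, and scipy-style gates: prominence floor
# then greedy minimum-distance enforcement from the highest peak down.
find_peaks <- function(signal, min_distance = 1L, min_prominence = 0) {
  n <- length(signal)
  if (n < 3L) return(integer(0))
  r <- rle(signal)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1L || i == k) next
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L])
      cand <- c(cand, as.integer((starts[i] + ends[i]) %/% 2L))
  }
  if (!length(cand)) return(integer(0))
  # prominence: drop to the highest of the two key saddles
  prom <- vapply(cand, function(p) {
    h <- signal[p]
    left_min <- h; i <- p
    while (i > 1L) {
      i <- i - 1L
      if (signal[i] > h) break
      if (signal[i] < left_min) left_min <- signal[i]
    }
    right_min <- h; i <- p
    while (i < n) {
      i <- i + 1L
      if (signal[i] > h) break
      if (signal[i] < right_min) right_min <- signal[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand) || min_distance <= 1L) return(sort(cand))
  ord <- order(signal[cand], decreasing = TRUE)
  taken <- logical(length(cand))
  for (i in ord) {
    if (any(taken & abs(cand - cand[i]) < min_distance)) next
    taken[i] <- TRUE
  }
  sort(cand[taken])
}

#' Respiration rate from gated local maxima
#'
#' Counts local maxima of the (already filtered) breath signal within the
#' most recent `window_s` seconds, gated by a minimum peak distance (default
#' 0.4 s, i.e. a 150 breaths/min ceiling) and a minimum prominence fraction
#' of the window's amplitude range, and converts the count to breaths per
#' minute.
#'
#' @param signal filtered 1-D breath signal.
#' @param rate_hz sampling rate (Hz).
#' @param window_s analysis window in seconds.
#' @param min_peak_distance_s minimum separation of counted maxima (s).
#' @param min_prominence_frac prominence floor as a fraction of the window
#'   amplitude range.
#' @return object of class `rate_estimate`: `rpm`, `peak_indices` (relative
#'   to the analyzed window), `window_s`.
#' @export
respiration_rate <- function(signal, rate_hz, window_s = 60,
                             min_peak_distance_s = 0.4,
                             min_prominence_frac = 0.1) {
  x <- as.numeric(signal)
  if (!length(x)) stopf("empty signal")
  assert_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  assert_scalar_num(window_s, "window_s", positive = TRUE)
  n <- length(x)
  if (n / rate_hz < window_s - 1e-9)
    stopf("signal spans %.3g s < window of %.3g s", n / rate_hz, window_s)
  nw <- min(n, round(window_s * rate_hz))
  xw <- x[(n - nw + 1L):n]
  rng <- diff(range(xw))
  peaks <- if (rng == 0) integer(0) else
    find_peaks(xw,
               min_distance = max(1L, round(min_peak_distance_s * rate_hz)),
               min_prominence = min_prominence_frac * rng)
  structure(list(rpm = 60 * length(peaks) / window_s,
                 peak_indices = peaks, window_s = window_s),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.2f breaths/min (%d peaks in %.3g s)\n",
              x$rpm, length(x$peak_indices), x$window_s))
  invisible(x)
}

#' Select the breathing axis of a recording
#'
#' Picks the axis with the largest spectral power in the respiration band
#' (0.1-1 Hz by default), the channel a chest sensor couples breathing into
#' most strongly.
#'
#' @param recording a [triaxial_recording()].
#' @param band numeric length-2 frequency band in Hz.
#' @return column index (1 = x, 2 = y, 3 = z).
#' @export
breathing_axis <- function(recording, band = c(0.1, 1)) {
  stopifnot(inherits(recording, "triaxial_recording"))
  fs <- if (is.null(recording$measured_rate_hz)) recording$nominal_rate_hz
        else recording$measured_rate_hz
  n <- nrow(recording$samples)
  freqs <- (seq_len(n) - 1) * fs / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  pw <- vapply(1:3, function(j) {
    s <- recording$samples[, j]
    sum(Mod(fft(s - mean(s)))[in_band]^2)
  }, numeric(1))
  which.max(pw)
}
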