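# Minimal IIR/FIR design used by the preprocessing stage.
#
# The lowpass Butterworth is designed directly as cascaded second-order
# sections (bilinear transform of the analog prototype, conjugate pole
# pairs), which stays numerically stable at order 10 with cutoffs far below
# Nyquist where a single transfer-function polynomial would not.

# Second-order-section matrix for a lowpass Butterworth.
# Returns a list of sections, each c(b0, b1, b2, a1, a2) with a0 = 1.
butter_lowpass_sos <- function(order, cutoff_hz, rate_hz) {
  if (order < 1L) stopf("filter order must be >= 1")
  if (rate_hz <= 2 * cutoff_hz)
    stopf("sampling rate must exceed twice the cutoff")
  K <- 2 * rate_hz
  wa <- K * tan(pi * cutoff_hz / rate_hz)  # prewarped analog cutoff
  k <- seq_len(order)
  poles <- wa * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  sos <- list()
  # conjugate pairs (poles come in conjugate order for even n; handle odd n
  # real pole separately)
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) < 1e-12 * abs(p)) {
      # first-order analog section wa / (s - p)
      used[i] <- TRUE
      d0 <- K - Re(p)
      sos[[length(sos) + 1L]] <- c(wa / d0, wa / d0, 0,
                                   (-K - Re(p)) / d0, 0)
    } else {
      j <- which(!used & abs(poles - Conj(p)) < 1e-6 * abs(p))[1]
      used[c(i, j)] <- TRUE
      A1 <- -2 * Re(p); A0 <- Mod(p)^2; B0 <- wa^2
      d0 <- K^2 + A1 * K + A0
      sos[[length(sos) + 1L]] <- c(B0 / d0, 2 * B0 / d0, B0 / d0,
                                   (2 * A0 - 2 * K^2) / d0,
                                   (K^2 - A1 * K + A0) / d0)
    }
  }
  sos
}

# Apply one biquad (direct form) using C-level stats::filter for both the
# MA and the AR part.
biquad_filter <- function(x, s) {
  v <- s[1] * x +
    s[2] * c(0, x[-length(x)]) +
    s[3] * c(0, 0, head(x, -2))
  as.numeric(stats::filter(v, filter = c(-s[4], -s[5]),
                           method = "recursive"))
}

sos_filter <- function(x, sos) {
  for (s in sos) x <- biquad_filter(x, s)
  x
}

# Forward-backward (zero-phase) SOS filtering with odd-reflection padding to
# suppress edge transients.
sos_filtfilt <- function(x, sos, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 500L)
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(left, x, right)
  } else xe <- x
  y <- sos_filter(xe, sos)
  y <- rev(sos_filter(rev(y), sos))
  y[(pad + 1):(pad + n)]
}

# Windowed-sinc (Hamming) lowpass FIR with unit DC gain.
# cutoff is normalized to Nyquist (0 < cutoff <= 1); returns 2*half+1 taps.
fir_lowpass <- function(cutoff, half) {
  m <- seq(-half, half)
  h <- cutoff * sinc(cutoff * m)
  w <- 0.54 + 0.46 * cos(pi * m / half)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Linear convolution via FFT (stats::convolve open type), keeping full length.
conv_full <- function(x, h) {
  convolve(x, rev(h), type = "open")
}

#' Best rational approximation by continued fractions
#'
#' Approximates a positive ratio by p/q with `q <= max_den` using the
#' continued-fraction convergents, as needed to turn a measured/nominal
#' sampling-rate ratio into a resampling fraction (e.g. 52.5/50 = 21/20).
#'
#' @param x positive ratio to approximate.
#' @param max_den largest admissible denominator.
#' @return integer vector c(p, q).
#' @export
best_rational <- function(x, max_den = 1000L) {
  assert_scalar_num(x, "x", positive = TRUE)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    frac <- b - a
    if (frac < 1e-12 || abs(h1 / k1 - x) < 1e-12 * x) break
    b <- 1 / frac
  }
  c(p = as.integer(round(h1)), q = as.integer(round(k1)))
}
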