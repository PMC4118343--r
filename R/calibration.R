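# Six-position least-squares accelerometer calibration.
#
# The sensor model is y = [w | 1] %*% X where w is a raw reading (row
# vector), y the corrected reading and X a 4x3 parameter matrix: a 3x3 gain
# block on top of a 1x3 offset row (12 parameters). The fit minimizes
# ||[w|1] X - y||^2 over captures at known orientations where y is a unit
# gravity vector.

#' Accelerometer gain/offset calibration model
#'
#' @param params 4x3 numeric matrix: rows 1-3 the gain block (g per raw
#'   unit), row 4 the offsets (g). Defaults to the identity model.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(params = rbind(diag(3), 0)) {
  params <- as.matrix(params)
  if (!all(dim(params) == c(4L, 3L)))
    stopf("calibration params must be a 4x3 matrix")
  if (!all(is.finite(params))) stopf("calibration params must be finite")
  if (abs(det(params[1:3, ])) <= 1e-12)
    stopf("calibration gain block is singular")
  structure(list(params = params), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> gains:\n")
  print(round(x$params[1:3, ], 6))
  cat("offsets:", paste(round(x$params[4, ], 6), collapse = " "), "\n")
  invisible(x)
}

#' Stationary calibration batch
#'
#' @param raw n x 3 matrix of averaged raw readings, one row per stationary
#'   capture (n >= 6).
#' @param gravity n x 3 matrix of the known normalized gravity vectors.
#' @return object of class `stationary_batch`.
#' @export
stationary_batch <- function(raw, gravity) {
  raw <- as.matrix(raw); gravity <- as.matrix(gravity)
  if (ncol(raw) != 3L || ncol(gravity) != 3L || nrow(raw) != nrow(gravity))
    stopf("raw and gravity must be n x 3 matrices of equal n")
  if (nrow(raw) < 6L) stopf("need at least 6 stationary captures")
  if (!all(is.finite(raw)) || !all(is.finite(gravity)))
    stopf("batch contains non-finite values")
  structure(list(raw = raw, gravity = gravity), class = "stationary_batch")
}

#' Fit the 12-parameter calibration by least squares
#'
#' Solves min_X ||[w | 1] X - y||^2 with the offset-estimating augmented
#' design, via QR (`lm.fit`) rather than explicit normal-equation inversion.
#'
#' @param batch a [stationary_batch()].
#' @return a [calibration_model()] with attribute `residual` (root mean
#'   squared fit residual).
#' @export
fit_calibration <- function(batch) {
  stopifnot(inherits(batch, "stationary_batch"))
  A <- cbind(batch$raw, 1)
  qrA <- qr(A)
  if (qrA$rank < 4L) {
    null_dir <- qr.Q(qr(t(A)), complete = TRUE)[, qrA$rank + 1L]
    stopf("rank-deficient stationary design (deficient direction ~ [%s])",
          paste(round(null_dir, 3), collapse = ", "))
  }
  X <- qr.coef(qrA, batch$gravity)
  res <- batch$gravity - A %*% X
  model <- calibration_model(X)
  attr(model, "residual") <- sqrt(mean(res^2))
  model
}

#' Apply a calibration model to a recording
#'
#' Replaces every sample row (ax, ay, az) with [ax ay az 1] X; timestamps
#' and rates are untouched.
#'
#' @param recording a [triaxial_recording()].
#' @param model a [calibration_model()].
#' @return the corrected [triaxial_recording()].
#' @export
apply_calibration <- function(recording, model) {
  stopifnot(inherits(recording, "triaxial_recording"),
            inherits(model, "calibration_model"))
  out <- cbind(recording$samples, 1) %*% model$params
  colnames(out) <- c("x", "y", "z")
  recording$samples <- out
  recording
}
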