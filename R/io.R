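# CSV / JSON / YAML readers and writers.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a triaxial recording to CSV
#'
#' Columns `time_s, ax_g, ay_g, az_g`, full double precision (lossless
#' round trip).
#'
#' @param recording a [triaxial_recording()].
#' @param path output file.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "triaxial_recording"))
  df <- data.frame(time_s = fmt_num(recording$times),
                   ax_g = fmt_num(recording$samples[, 1]),
                   ay_g = fmt_num(recording$samples[, 2]),
                   az_g = fmt_num(recording$samples[, 3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a triaxial recording from CSV
#'
#' Expects the header `time_s, ax_g, ay_g, az_g`; malformed rows raise a
#' parse error naming the first bad line, non-monotone timestamps a data
#' error.
#'
#' @param path CSV file.
#' @param nominal_rate_hz nominal rate; inferred from the median timestamp
#'   spacing when `NULL`.
#' @return a [triaxial_recording()].
#' @export
read_recording <- function(path, nominal_rate_hz = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- tryCatch(read.csv(path, colClasses = "character"),
                 error = function(e) stopf("parse error in %s: %s",
                                           path, conditionMessage(e)))
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  if (!nrow(df)) stopf("parse error: %s is empty", path)
  num <- suppressWarnings(
    vapply(need, function(cn) as.numeric(df[[cn]]),
           numeric(nrow(df))))
  num <- matrix(num, ncol = 4L,
                dimnames = list(NULL, need))
  bad <- which(!stats::complete.cases(num))
  if (length(bad))
    stopf("parse error in %s at data line %d", path, bad[1])
  tt <- num[, "time_s"]
  if (nrow(num) > 1L && any(diff(tt) <= 0))
    stopf("data error in %s: timestamps not strictly increasing (line %d)",
          path, which(diff(tt) <= 0)[1] + 1L)
  if (is.null(nominal_rate_hz)) {
    nominal_rate_hz <- if (nrow(num) > 1L) 1 / stats::median(diff(tt)) else 1
  }
  triaxial_recording(times = tt, samples = num[, c("ax_g", "ay_g", "az_g")],
                     nominal_rate_hz = nominal_rate_hz)
}

#' Write a 1-D waveform to CSV (`time_s,value`)
#' @param waveform a `breath_waveform` or list with `times`/`series`.
#' @param path output file.
#' @export
write_waveform <- function(waveform, path) {
  df <- data.frame(time_s = fmt_num(waveform$times),
                   value = fmt_num(waveform$series))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 1-D waveform from CSV
#' @param path CSV with columns `time_s,value`.
#' @return list with `times` and `series`.
#' @export
read_waveform <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stopf("%s: expected columns time_s, value", path)
  list(times = as.numeric(df$time_s), series = as.numeric(df$value))
}

#' Serialize a calibration model to JSON
#'
#' Named keys `acc11..acc33` for the gain block (row-major) and
#' `acc10, acc20, acc30` for the offsets.
#'
#' @param model a [calibration_model()].
#' @param path output JSON file.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  p <- model$params
  obj <- list()
  for (i in 1:3) for (j in 1:3)
    obj[[sprintf("acc%d%d", i, j)]] <- p[i, j]
  for (j in 1:3) obj[[sprintf("acc%d0", j)]] <- p[4, j]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path JSON file written by [write_calibration_json()].
#' @return a [calibration_model()].
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- matrix(0, 4, 3)
  for (i in 1:3) for (j in 1:3) p[i, j] <- obj[[sprintf("acc%d%d", i, j)]]
  for (j in 1:3) p[4, j] <- obj[[sprintf("acc%d0", j)]]
  calibration_model(p)
}

#' Write a stationary calibration batch to CSV
#' @param batch a [stationary_batch()].
#' @param path output file.
#' @export
write_batch_csv <- function(batch, path) {
  df <- data.frame(raw_x = fmt_num(batch$raw[, 1]),
                   raw_y = fmt_num(batch$raw[, 2]),
                   raw_z = fmt_num(batch$raw[, 3]),
                   g_x = fmt_num(batch$gravity[, 1]),
                   g_y = fmt_num(batch$gravity[, 2]),
                   g_z = fmt_num(batch$gravity[, 3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stationary calibration batch from CSV
#' @param path file written by [write_batch_csv()].
#' @return a [stationary_batch()].
#' @export
read_batch_csv <- function(path) {
  df <- read.csv(path)
  stationary_batch(raw = as.matrix(df[, c("raw_x", "raw_y", "raw_z")]),
                   gravity = as.matrix(df[, c("g_x", "g_y", "g_z")]))
}

#' Serialize a trained hierarchical classifier to JSON
#' @param classifier a [train_hierarchy()] fit.
#' @param path output JSON file.
#' @export
write_classifier_json <- function(classifier, path) {
  stopifnot(inherits(classifier, "hierarchical_classifier"))
  ser_svm <- function(m) list(
    support_vectors = unname(as.matrix(m$support_vectors)),
    alphas = m$alphas, sv_labels = m$sv_labels, bias = m$bias,
    kernel = unclass(m$kernel),
    center = m$scaling$center, scale = m$scaling$scale,
    feature_names = m$feature_names)
  obj <- list(
    classes = classifier$tree$classes,
    branches = lapply(seq_along(classifier$tree$branches), function(i) {
      b <- classifier$tree$branches[[i]]
      f <- classifier$branch_fits[[i]]
      list(left = b$left, right = b$right, features = f$features,
           accuracy = f$accuracy, svm = ser_svm(f$model))
    }),
    kernel = unclass(classifier$kernel))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hierarchical classifier from JSON
#' @param path file written by [write_classifier_json()].
#' @return a `hierarchical_classifier`.
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mk_kernel <- function(k) kernel_spec(k$kind, sigma = k$sigma,
                                       degree = k$degree, coef0 = k$coef0)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  branches <- lapply(obj$branches, function(b)
    list(left = chr(b$left), right = chr(b$right)))
  fits <- lapply(obj$branches, function(b) {
    s <- b$svm
    sv <- do.call(rbind, lapply(s$support_vectors, num))
    model <- structure(list(
      support_vectors = sv, alphas = num(s$alphas),
      sv_labels = num(s$sv_labels), bias = as.numeric(s$bias),
      kernel = mk_kernel(s$kernel),
      scaling = list(center = num(s$center), scale = num(s$scale)),
      n_features = ncol(sv), feature_names = chr(s$feature_names)),
      class = "binary_svm")
    list(features = chr(b$features), accuracy = as.numeric(b$accuracy),
         model = model)
  })
  report <- data.frame(
    branch = seq_along(fits),
    f1 = vapply(fits, function(f) f$features[1], character(1)),
    f2 = vapply(fits, function(f) f$features[2], character(1)),
    accuracy = vapply(fits, function(f) f$accuracy, numeric(1)))
  structure(list(tree = tree_spec(branches), branch_fits = fits,
                 report = report, kernel = mk_kernel(obj$kernel),
                 feature_cols = NULL, is_train = NULL, seed = NULL),
            class = "hierarchical_classifier")
}

#' Write a feature table to CSV
#' @param features data.frame from [extract_feature_matrix()].
#' @param path output file.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV file; the header carries the feature names.
#' @return data.frame.
#' @export
read_features_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
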