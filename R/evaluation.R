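# Confusion accounting and binary (normal vs impaired) metrics.

#' Confusion counts
#'
#' Fractional values are allowed so that subject-averaged tables can be
#' represented directly.
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(!is.finite(v)) || any(v < 0))
    stopf("confusion counts must be finite and non-negative")
  if (sum(v) <= 0) stopf("confusion counts sum to zero")
  structure(as.list(v), class = "confusion_counts")
}

#' Binary confusion from multi-class predictions
#'
#' Collapses six-class predictions to healthy (positive = the normal
#' pattern) versus impaired (any other pattern) before counting.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive_class the positive (healthy) label.
#' @return a [confusion_counts()].
#' @export
confusion_binary <- function(predicted, truth, positive_class = "normal") {
  if (!length(predicted) || length(predicted) != length(truth))
    stopf("predicted and truth must be non-empty and of equal length")
  p <- predicted == positive_class
  t <- truth == positive_class
  confusion_counts(TP = sum(p & t), TN = sum(!p & !t),
                   FP = sum(p & !t), FN = sum(!p & t))
}

#' Sensitivity, specificity, accuracy and G-mean
#'
#' `sens = TP/(TP+FN)`, `spec = TN/(TN+FP)`,
#' `acc = (TP+TN)/(TP+TN+FP+FN)`, `gmean = sqrt(sens * spec)`. Values are
#' returned at full precision; round only for display.
#'
#' @param counts a [confusion_counts()].
#' @return object of class `metric_set`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (TP + FN <= 0) stopf("undefined sensitivity: no positive cases")
    if (TN + FP <= 0) stopf("undefined specificity: no negative cases")
    sens <- TP / (TP + FN)
    spec <- TN / (TN + FP)
    structure(list(sensitivity = sens, specificity = spec,
                   accuracy = (TP + TN) / (TP + TN + FP + FN),
                   gmean = sqrt(sens * spec)),
              class = "metric_set")
  })
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> sens %.2f  spec %.2f  acc %.2f  G-mean %.2f\n",
    x$sensitivity, x$specificity, x$accuracy, x$gmean))
  invisible(x)
}

#' Cohort mean and sample standard deviation
#'
#' @param ages numeric vector (n >= 2) of ages in years.
#' @return list with `mean` and `sd` (1/(n-1) normalization).
#' @export
cohort_stats <- function(ages) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L) stopf("need at least two ages")
  list(mean = mean(ages), sd = sd(ages))
}

#' Evaluate the hierarchical classifier per subject or pooled
#'
#' Case 1 trains and tests one classifier per subject on that subject's own
#' windows and averages six-class accuracy, binary counts and metrics
#' across subjects (counts may be fractional). Case 2 trains a single
#' pooled classifier over all subjects. Both use a stratified 70/30 split
#' under the seed.
#'
#' @param features feature table with `label`, `subject` and feature
#'   columns (as from [study_feature_table()]).
#' @param tree,kernel,train_frac,C,scorer see [train_hierarchy()].
#' @param mode "case1" (per subject) or "case2" (pooled).
#' @param seed split seed.
#' @param positive_class healthy class for the binary collapse.
#' @return report list: `mode`, `six_class_accuracy`, `counts`, `metrics`,
#'   and for case 1 a `per_subject` table.
#' @export
evaluate_case <- function(features, tree = default_tree(),
                          kernel = kernel_spec(), mode = c("case1", "case2"),
                          seed = 1L, train_frac = 0.7, C = 1e3,
                          scorer = "training", positive_class = "normal") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(features),
            all(c("label", "subject") %in% names(features)))
  eval_one <- function(df, s) {
    clf <- train_hierarchy(df, tree, kernel, train_frac, seed = s,
                           C = C, scorer = scorer)
    test <- df[!clf$is_train, , drop = FALSE]
    if (!nrow(test)) return(NULL)
    pred <- predict(clf, test)
    cnt <- confusion_binary(pred, test$label, positive_class)
    list(acc6 = mean(pred == test$label), counts = cnt,
         metrics = classification_metrics(cnt), classifier = clf,
         n_test = nrow(test))
  }
  if (mode == "case2") {
    r <- eval_one(features, seed)
    return(list(mode = "case2", six_class_accuracy = r$acc6,
                counts = r$counts, metrics = r$metrics,
                classifier = r$classifier, n_test = r$n_test))
  }
  subjects <- sort(unique(features$subject))
  per <- list()
  for (s in subjects) {
    df <- features[features$subject == s, , drop = FALSE]
    res <- tryCatch(eval_one(df, derive_seed(seed, s)),
                    error = function(e) NULL)
    if (is.null(res)) {
      message("subject ", s, " excluded (no evaluable test rows)")
      next
    }
    per[[as.character(s)]] <- res
  }
  if (!length(per)) stopf("no subject could be evaluated")
  tab <- do.call(rbind, lapply(names(per), function(s) {
    r <- per[[s]]
    data.frame(subject = s, acc6 = r$acc6,
               TP = r$counts$TP, TN = r$counts$TN,
               FP = r$counts$FP, FN = r$counts$FN,
               sensitivity = r$metrics$sensitivity,
               specificity = r$metrics$specificity,
               accuracy = r$metrics$accuracy, gmean = r$metrics$gmean)
  }))
  avg_counts <- confusion_counts(TP = mean(tab$TP), TN = mean(tab$TN),
                                 FP = mean(tab$FP), FN = mean(tab$FN))
  list(mode = "case1",
       six_class_accuracy = mean(tab$acc6),
       counts = avg_counts,
       metrics = list(sensitivity = mean(tab$sensitivity),
                      specificity = mean(tab$specificity),
                      accuracy = mean(tab$accuracy),
                      gmean = mean(tab$gmean)),
       per_subject = tab)
}
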