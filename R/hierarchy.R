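# Hierarchical SVM classification tree: five binary branches over six
# breathing-pattern classes, with exhaustive per-branch feature-pair
# selection by training accuracy.

#' Default six-class classification tree
#'
#' Root separates the four 2-minute patterns (normal, bradypnea, tachypnea,
#' Cheyne-Stokes — the "G11" group) from the two 1-minute patterns
#' (Kussmaul, Biot's — "G12"); below the root, slow patterns split from
#' fast ones, then leaves. Five branches, six leaves; fully overridable via
#' [tree_spec()].
#'
#' @return a `tree_spec`.
#' @export
default_tree <- function() {
  tree_spec(list(
    list(left = c("normal", "bradapnea", "tachypnea", "cheyne_stokes"),
         right = c("kussmaul", "biots")),
    list(left = c("normal", "bradapnea"),
         right = c("tachypnea", "cheyne_stokes")),
    list(left = "normal", right = "bradapnea"),
    list(left = "tachypnea", right = "cheyne_stokes"),
    list(left = "kussmaul", right = "biots")
  ))
}

#' Build and validate a classification-tree specification
#'
#' Each branch is `list(left = classes, right = classes, features =
#' optional fixed pair)`. The branch set must form a proper binary
#' partition tree: every internal class set is split by exactly one branch,
#' left and right are disjoint, and every class ends in its own leaf.
#'
#' @param branches list of branches, root first.
#' @return object of class `tree_spec`.
#' @export
tree_spec <- function(branches) {
  if (!length(branches)) stopf("empty tree")
  classes <- sort(unique(unlist(lapply(branches, function(b)
    c(b$left, b$right)))))
  key <- function(s) paste(sort(s), collapse = "|")
  by_parent <- new.env()
  for (b in branches) {
    if (!length(b$left) || !length(b$right))
      stopf("branch with an empty side")
    if (length(intersect(b$left, b$right)))
      stopf("branch sides overlap: %s",
            paste(intersect(b$left, b$right), collapse = ", "))
    k <- key(c(b$left, b$right))
    if (!is.null(by_parent[[k]])) stopf("duplicate branch for set {%s}", k)
    by_parent[[k]] <- b
  }
  # walk from the root: every non-singleton set must have a branch
  pending <- list(classes)
  n_used <- 0L
  while (length(pending)) {
    s <- pending[[1]]; pending <- pending[-1]
    if (length(s) == 1L) next
    b <- by_parent[[key(s)]]
    if (is.null(b)) stopf("no branch partitions the set {%s}", key(s))
    n_used <- n_used + 1L
    pending <- c(pending, list(b$left), list(b$right))
  }
  if (n_used != length(branches))
    stopf("tree has unreachable branches (%d of %d used)",
          n_used, length(branches))
  structure(list(branches = branches, classes = classes),
            class = "tree_spec")
}

branch_for_set <- function(tree, s) {
  key <- paste(sort(s), collapse = "|")
  for (i in seq_along(tree$branches)) {
    b <- tree$branches[[i]]
    if (paste(sort(c(b$left, b$right)), collapse = "|") == key)
      return(i)
  }
  stopf("no branch for class set {%s}", key)
}

# Stratified deterministic train/test split: floor(frac * n) training rows
# per stratum, sampled under the seed.
stratified_split <- function(strata, frac = 0.7, seed = 1L) {
  is_train <- logical(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_tr <- floor(frac * length(idx))
      is_train[sample(idx, n_tr)] <- TRUE
    }
  })
  is_train
}

#' Exhaustive feature-pair selection for one branch
#'
#' Trains an SVM on every unordered pair of candidate features and scores
#' it on the same training rows (training set = validation set, the
#' optimistic convention of per-branch selection); returns the pair with
#' the best training accuracy, breaking ties toward the lexicographically
#' first pair. An optional k-fold scorer is available but off by default.
#'
#' @param X training feature matrix (columns named).
#' @param y branch labels in {-1, +1}.
#' @param pool_cols candidate feature (column) names.
#' @param kernel a [kernel_spec()].
#' @param C SVM penalty.
#' @param scorer "training" or "cv".
#' @param cv_folds folds for the cv scorer.
#' @return list with `features`, `accuracy`, `model`.
#' @export
select_branch_features <- function(X, y, pool_cols = colnames(X),
                                   kernel = kernel_spec(), C = 1e3,
                                   scorer = c("training", "cv"),
                                   cv_folds = 5L) {
  scorer <- match.arg(scorer)
  X <- as.matrix(X)
  if (sum(y == 1) < 2L || sum(y == -1) < 2L)
    stopf("need at least 2 rows on each branch side")
  pool_cols <- sort(pool_cols)
  if (length(pool_cols) < 2L) stopf("need at least two candidate features")
  pairs <- utils::combn(pool_cols, 2L)
  best <- list(accuracy = -Inf)
  for (j in seq_len(ncol(pairs))) {
    cols <- pairs[, j]
    Xp <- X[, cols, drop = FALSE]
    acc <- tryCatch({
      if (scorer == "training") {
        fit <- train_binary_svm(Xp, y, kernel, C = C)
        mean(svm_predict(fit, Xp)$label == y)
      } else {
        folds <- rep_len(seq_len(cv_folds), length(y))
        hits <- vapply(seq_len(cv_folds), function(f) {
          tr <- folds != f
          if (length(unique(y[tr])) < 2L) return(NA_real_)
          fit <- train_binary_svm(Xp[tr, , drop = FALSE], y[tr], kernel, C = C)
          mean(svm_predict(fit, Xp[!tr, , drop = FALSE])$label == y[!tr])
        }, numeric(1))
        mean(hits, na.rm = TRUE)
      }
    }, error = function(e) -Inf)
    if (acc > best$accuracy + 1e-12) {
      best <- list(features = cols, accuracy = acc)
    }
  }
  if (!is.finite(best$accuracy)) stopf("no feature pair could be trained")
  best$model <- train_binary_svm(X[, best$features, drop = FALSE], y,
                                 kernel, C = C)
  if (scorer == "training")
    best$accuracy <- mean(svm_predict(best$model,
                                      X[, best$features, drop = FALSE])$label == y)
  best
}

#' Train the hierarchical breathing-pattern classifier
#'
#' Splits the labelled feature table 70/30 (stratified per class, and per
#' subject when a `subject` column is present), then per branch relabels
#' the training rows +1 (left side) / -1 (right side), selects the best
#' feature pair exhaustively and fits the final branch SVM on it.
#'
#' @param features data.frame with a `label` column, feature columns, and
#'   optionally `subject`.
#' @param tree a [tree_spec()].
#' @param kernel a [kernel_spec()].
#' @param train_frac training fraction of the split.
#' @param seed split seed.
#' @param feature_cols candidate columns (defaults to every numeric column
#'   that is not bookkeeping).
#' @param C SVM penalty.
#' @param scorer selection scorer, see [select_branch_features()].
#' @return object of class `hierarchical_classifier` with per-branch
#'   models, selected features, the training report, and the split.
#' @export
train_hierarchy <- function(features, tree = default_tree(),
                            kernel = kernel_spec(), train_frac = 0.7,
                            seed = 1L, feature_cols = NULL, C = 1e3,
                            scorer = "training") {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  missing_cls <- setdiff(tree$classes, unique(features$label))
  if (length(missing_cls))
    stopf("classes absent from data: %s",
          paste(missing_cls, collapse = ", "))
  if (is.null(feature_cols)) {
    drop <- c("label", "subject", "window", "start_s")
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))], drop)
  }
  strata <- if ("subject" %in% names(features))
    paste(features$subject, features$label) else features$label
  is_train <- stratified_split(strata, train_frac, seed)
  train <- features[is_train, , drop = FALSE]
  X <- as.matrix(train[, feature_cols, drop = FALSE])
  fits <- vector("list", length(tree$branches))
  report <- data.frame(branch = seq_along(tree$branches),
                       f1 = NA_character_, f2 = NA_character_,
                       accuracy = NA_real_)
  for (i in seq_along(tree$branches)) {
    b <- tree$branches[[i]]
    in_branch <- train$label %in% c(b$left, b$right)
    y <- ifelse(train$label[in_branch] %in% b$left, 1, -1)
    Xb <- X[in_branch, , drop = FALSE]
    if (!is.null(b$features)) {
      fit <- train_binary_svm(Xb[, b$features, drop = FALSE], y, kernel,
                              C = C)
      sel <- list(features = b$features,
                  accuracy = mean(svm_predict(fit,
                    Xb[, b$features, drop = FALSE])$label == y),
                  model = fit)
    } else {
      sel <- select_branch_features(Xb, y, feature_cols, kernel, C = C,
                                    scorer = scorer)
    }
    fits[[i]] <- sel
    report$f1[i] <- sel$features[1]
    report$f2[i] <- sel$features[2]
    report$accuracy[i] <- sel$accuracy
  }
  structure(list(tree = tree, branch_fits = fits, report = report,
                 kernel = kernel, feature_cols = feature_cols,
                 is_train = is_train, seed = seed),
            class = "hierarchical_classifier")
}

#' Classify one feature row through the tree
#'
#' Descends from the root: each branch SVM routes the row to its left
#' (+1) or right (-1) class set until a single leaf label remains.
#'
#' @param classifier a [train_hierarchy()] fit.
#' @param row named numeric vector or one-row data.frame containing every
#'   selected feature.
#' @return a single class label.
#' @export
classify_window <- function(classifier, row) {
  stopifnot(inherits(classifier, "hierarchical_classifier"))
  if (is.data.frame(row)) row <- unlist(row[1, , drop = TRUE])
  current <- classifier$tree$classes
  while (length(current) > 1L) {
    i <- branch_for_set(classifier$tree, current)
    fit <- classifier$branch_fits[[i]]
    miss <- setdiff(fit$features, names(row))
    if (length(miss)) stopf("missing feature '%s'", miss[1])
    v <- svm_predict(fit$model, as.numeric(row[fit$features]))$label
    b <- classifier$tree$branches[[i]]
    current <- if (v > 0) b$left else b$right
  }
  current
}

#' Predict labels for a feature table
#'
#' @param object a `hierarchical_classifier`.
#' @param newdata data.frame of feature rows.
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.hierarchical_classifier <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i)
    classify_window(object, newdata[i, , drop = FALSE]), character(1))
}

#' @export
print.hierarchical_classifier <- function(x, ...) {
  cat(sprintf("<hierarchical_classifier> %d branches, %s kernel\n",
              length(x$branch_fits), x$kernel$kind))
  print(x$report, row.names = FALSE)
  invisible(x)
}
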