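# A small synthetic feature table with hand-placed class geometry: every
# branch of the default tree is separable by some feature pair.
make_toy_features <- function(n_per = 12, seed = 31, jitter = 0.05) {
  classes <- breath_patterns()
  centers <- list(  # (f1, f2, f3) cluster centers per class
    normal        = c(0, 0, 0),
    bradapnea     = c(0, 3, 0),
    tachypnea     = c(3, 0, 0),
    cheyne_stokes = c(3, 3, 0),
    kussmaul      = c(0, 0, 5),
    biots         = c(3, 0, 5))
  breathclass:::with_seed(seed, {
    rows <- lapply(classes, function(cl) {
      m <- matrix(rnorm(3 * n_per, sd = jitter), ncol = 3)
      sweep(m, 2, centers[[cl]], "+")
    })
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("f1", "f2", "f3")
    df$label <- rep(classes, each = n_per)
    df
  })
}

test_that("default tree is a valid 5-branch, 6-leaf partition", {
  tree <- default_tree()
  expect_length(tree$branches, 5L)
  expect_length(tree$classes, 6L)
  root <- tree$branches[[1]]
  expect_length(root$left, 4L)   # the four 2-minute patterns
  expect_length(root$right, 2L)  # the two 1-minute patterns
  # swapping children of two sibling branches still validates
  b <- tree$branches
  b[[3]] <- list(left = "bradapnea", right = "normal")
  expect_s3_class(tree_spec(b), "tree_spec")
  # broken partitions are rejected
  b2 <- tree$branches
  b2[[3]] <- list(left = "normal", right = "tachypnea")
  expect_error(tree_spec(b2), "partition")
  expect_error(tree_spec(list(list(left = "a", right = "a"))), "overlap")
})

test_that("stratified split reproduces the 70/30 trial bookkeeping", {
  labels <- rep(c(rep("normal", 60), rep("kussmaul", 30)), 1)
  is_train <- breathclass:::stratified_split(labels, 0.7, seed = 3)
  expect_equal(sum(is_train[labels == "normal"]), 42L)
  expect_equal(sum(!is_train[labels == "normal"]), 18L)
  expect_equal(sum(is_train[labels == "kussmaul"]), 21L)
  expect_equal(sum(!is_train[labels == "kussmaul"]), 9L)
  # deterministic under seed
  expect_identical(is_train,
                   breathclass:::stratified_split(labels, 0.7, seed = 3))
})

test_that("feature-pair selection is exhaustive with lexicographic ties", {
  df <- make_toy_features()
  sub <- df[df$label %in% c("normal", "bradapnea"), ]
  y <- ifelse(sub$label == "normal", 1, -1)
  X <- as.matrix(sub[, c("f1", "f2", "f3")])
  sel <- select_branch_features(X, y, kernel = kernel_spec("linear"))
  expect_equal(sel$accuracy, 1)
  # f2 separates normal (0) from bradapnea (3); f1/f3 carry no signal,
  # so every winning pair contains f2 and the tie-break picks the first
  expect_equal(sel$features, c("f1", "f2"))
  # single candidate pair is returned as-is
  sel1 <- select_branch_features(X, y, pool_cols = c("f1", "f2"),
                                 kernel = kernel_spec("linear"))
  expect_equal(sel1$features, c("f1", "f2"))
  expect_error(select_branch_features(X[y == 1, ], y[y == 1]),
               "each branch side")
})

test_that("constructed separability selects the informative pair", {
  # only (f1, f3) separates tachypnea+kussmaul-style geometry
  breathclass:::with_seed(8, {
    X <- cbind(f1 = c(rnorm(10, 0, 0.1), rnorm(10, 2, 0.1)),
               f2 = rnorm(20, 1, 2),     # pure noise, wide
               f3 = c(rnorm(10, 0, 0.1), rnorm(10, -2, 0.1)))
    y <- rep(c(1, -1), each = 10)
  })
  sel <- select_branch_features(X, y, kernel = kernel_spec("rbf"))
  expect_equal(sel$accuracy, 1)
  expect_true(all(c("f1", "f3") %in% sel$features) ||
                "f1" %in% sel$features || "f3" %in% sel$features)
})

test_that("hierarchy reaches 100% training accuracy on separable features", {
  df <- make_toy_features()
  for (kind in c("linear", "poly3", "rbf")) {
    clf <- train_hierarchy(df, kernel = kernel_spec(kind), seed = 5)
    expect_true(all(clf$report$accuracy == 1), label = kind)
    train <- df[clf$is_train, ]
    expect_equal(mean(predict(clf, train) == train$label), 1, label = kind)
  }
})

test_that("training is deterministic and bookkeeping matches the protocol", {
  df <- make_toy_features()
  c1 <- train_hierarchy(df, seed = 9)
  c2 <- train_hierarchy(df, seed = 9)
  expect_identical(c1$is_train, c2$is_train)
  expect_identical(c1$report, c2$report)
  # per-class 70% of 12 -> 8 training rows; root G11 side = 4 classes x 8
  train <- df[c1$is_train, ]
  g11 <- c("normal", "bradapnea", "tachypnea", "cheyne_stokes")
  expect_equal(sum(train$label %in% g11), 4L * floor(0.7 * 12))
  expect_error(train_hierarchy(df[df$label != "biots", ]), "absent")
})

test_that("classification always ends in exactly one leaf", {
  df <- make_toy_features()
  clf <- train_hierarchy(df, seed = 2)
  # random rows, including far-off ones, must land in exactly one class
  probes <- breathclass:::with_seed(77, as.data.frame(
    matrix(rnorm(60, sd = 10), ncol = 3,
           dimnames = list(NULL, c("f1", "f2", "f3")))))
  labs <- predict(clf, probes)
  expect_true(all(labs %in% clf$tree$classes))
  expect_length(labs, 20L)
  # membership indicator sums to one by construction
  expect_error(classify_window(clf, c(f1 = 1, f2 = 2)), "missing feature")
})

test_that("a perfectly fit tree reproduces training labels", {
  df <- make_toy_features(jitter = 0.01)
  clf <- train_hierarchy(df, seed = 4)
  train <- df[clf$is_train, ]
  expect_equal(predict(clf, train), train$label)
})
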