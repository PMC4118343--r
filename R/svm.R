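# Binary maximal-margin SVM solved in the Lagrangian dual.
#
# The dual QP  max_a  sum a - 1/2 a' (yy' * K) a,  s.t.  y'a = 0,
# 0 <= a <= C  is solved with quadprog; C defaults large (1e3) so the
# hard-margin solution is recovered on separable data while noisy feature
# sets remain solvable. Features are standardized before kernel evaluation
# so that an RBF bandwidth of sigma = 1 is meaningful across heterogeneous
# feature scales.

#' Kernel specification
#'
#' @param kind "linear" (`x.y`), "poly3" (`(x.y + 1)^3`) or "rbf"
#'   (`exp(-||x-y||^2 / (2 sigma^2))`).
#' @param sigma RBF bandwidth (> 0).
#' @param degree,coef0 polynomial degree and additive constant.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "poly3"), sigma = 1,
                        degree = 3, coef0 = 1) {
  kind <- match.arg(kind)
  assert_scalar_num(sigma, "sigma", positive = TRUE)
  structure(list(kind = kind, sigma = sigma, degree = degree, coef0 = coef0),
            class = "kernel_spec")
}

#' Evaluate a kernel between two vectors
#'
#' @param spec a [kernel_spec()].
#' @param xi,xj numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, xi, xj) {
  if (length(xi) != length(xj)) stopf("kernel inputs of unequal dimension")
  kernel_matrix(spec, matrix(xi, 1), matrix(xj, 1))[1, 1]
}

kernel_matrix <- function(spec, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  switch(spec$kind,
    linear = X %*% t(Y),
    poly3 = (X %*% t(Y) + spec$coef0)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * spec$sigma^2))
    })
}

#' Train a binary SVM in the dual
#'
#' @param X numeric matrix of feature rows.
#' @param y labels in {-1, +1}, both classes present.
#' @param kernel a [kernel_spec()].
#' @param C box penalty (large default approximates the hard margin).
#' @param tol KKT tolerance.
#' @param scale standardize columns before kernel evaluation.
#' @return object of class `binary_svm`: support vectors (in scaled space),
#'   `alphas`, `sv_labels`, `bias`, `kernel`, `scaling`.
#' @export
train_binary_svm <- function(X, y, kernel = kernel_spec(), C = 1e3,
                             tol = 1e-6, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stopf("X and y length mismatch")
  if (!all(y %in% c(-1, 1))) stopf("labels must be -1/+1")
  if (length(unique(y)) < 2L) stopf("invalid labels: single-class input")
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  sig[!is.finite(sig) | sig == 0] <- 1
  if (!scale) { mu <- rep(0, ncol(X)); sig <- rep(1, ncol(X)) }
  Xs <- sweep(sweep(X, 2, mu), 2, sig, "/")
  K <- kernel_matrix(kernel, Xs, Xs)
  D <- (y %o% y) * K
  d <- rep(1, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  # a singular kernel matrix (e.g. low-rank linear kernels) makes the dual
  # degenerate; grow the ridge until the solver returns a feasible solution
  alpha <- NULL
  ridge <- 1e-8 * max(1, mean(diag(K)))
  for (attempt in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(D + diag(ridge, n), d, A, b0, meq = 1),
      error = function(e) e)
    if (!inherits(sol, "error")) {
      cand <- pmin(pmax(sol$solution, 0), C)
      feasible <- max(abs(cand - sol$solution)) <= 1e-6 * max(1, max(cand)) &&
        abs(sum(cand * y)) <= 1e-6 * max(1, sum(cand))
      if (feasible) { alpha <- cand; break }
    }
    ridge <- ridge * 100
  }
  if (is.null(alpha))
    stopf("dual QP failed to converge after 6 ridge attempts")
  if (abs(sum(alpha * y)) > 1e-4 * max(1, sum(alpha)))
    stopf("dual solution violates sum(alpha * y) = 0")
  # polish: re-solve the KKT equalities exactly on the identified free set,
  # which removes the ridge-induced bias from the multipliers
  thr <- max(tol, 1e-7) * max(alpha)
  free <- which(alpha > thr & alpha < C * (1 - 1e-6))
  atC <- which(alpha >= C * (1 - 1e-6))
  if (length(free)) {
    Q <- D
    Akkt <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                  c(y[free], 0))
    rhs <- c(rep(1, length(free)) - (if (length(atC))
      as.numeric(Q[free, atC, drop = FALSE] %*% rep(C, length(atC))) else 0),
      -C * sum(y[atC]))
    polish <- tryCatch(solve(Akkt, rhs), error = function(e) NULL)
    if (!is.null(polish)) {
      af <- polish[seq_along(free)]
      if (all(af > -1e-9) && all(af < C + 1e-9)) {
        cand <- alpha
        cand[free] <- pmin(pmax(af, 0), C)
        if (abs(sum(cand * y)) <= 1e-8 * max(1, sum(cand)))
          alpha <- cand
      }
    }
  }
  f0 <- as.numeric(K %*% (alpha * y))
  sv <- alpha > max(tol, 1e-7) * max(alpha)
  margin_sv <- sv & alpha < C * (1 - 1e-6)
  bias <- if (any(margin_sv)) mean(y[margin_sv] - f0[margin_sv])
          else -(max(f0[y == -1]) + min(f0[y == 1])) / 2
  structure(list(support_vectors = Xs[sv, , drop = FALSE],
                 alphas = alpha[sv], sv_labels = y[sv], bias = bias,
                 kernel = kernel,
                 scaling = list(center = mu, scale = sig),
                 n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "binary_svm")
}

#' Decision values and labels of a binary SVM
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` evaluated after applying the
#' stored feature scaling; the sign is the predicted label.
#'
#' @param model a [train_binary_svm()] fit.
#' @param X matrix (or vector) of rows to classify.
#' @return list with `label` (+1/-1) and `decision` (raw values).
#' @export
svm_predict <- function(model, X) {
  stopifnot(inherits(model, "binary_svm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stopf("expected %d features, got %d", model$n_features, ncol(X))
  Xs <- sweep(sweep(X, 2, model$scaling$center), 2, model$scaling$scale, "/")
  K <- kernel_matrix(model$kernel, Xs, model$support_vectors)
  f <- as.numeric(K %*% (model$alphas * model$sv_labels)) + model$bias
  list(label = ifelse(f >= 0, 1, -1), decision = f)
}

#' @export
print.binary_svm <- function(x, ...) {
  cat(sprintf("<binary_svm> %s kernel, %d support vectors, bias %.4g\n",
              x$kernel$kind, length(x$alphas), x$bias))
  invisible(x)
}
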