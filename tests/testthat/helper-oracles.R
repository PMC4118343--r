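# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (double loops, exhaustive enumeration) and share no
# code with the package internals.

# Count strict local maxima of a noiseless series by sign changes of the
# first difference.
oracle_peak_count <- function(x) {
  d <- sign(diff(x))
  # collapse zero runs (plateaus) onto the preceding slope
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(d[-length(d)] == 1 & d[-1] == -1)
}

# Brute-force ApEn: explicit double loop over all template pairs, Chebyshev
# distance, self-matches included, finite-sample denominators.
oracle_apen <- function(u, m, r) {
  n <- length(u)
  phi <- function(mm) {
    N <- n - mm + 1L
    cs <- numeric(N)
    for (i in seq_len(N)) {
      cnt <- 0L
      for (j in seq_len(N)) {
        dmax <- 0
        for (k in 0:(mm - 1L)) {
          d <- abs(u[i + k] - u[j + k])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1L
      }
      cs[i] <- cnt / N
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1L)
}

# Exhaustive lag scan using plain cor() at every candidate shift.
oracle_best_lag <- function(a, b, max_lag) {
  best <- -Inf; best_l <- 0L
  for (l in seq(-max_lag, max_lag)) {
    if (l >= 0) {
      n <- min(length(a), length(b) - l)
      cc <- cor(a[1:n], b[(1 + l):(n + l)])
    } else {
      n <- min(length(b), length(a) + l)
      cc <- cor(a[(1 - l):(n - l)], b[1:n])
    }
    if (is.na(cc)) next
    if (cc > best + 1e-12 || (cc >= best - 1e-12 && abs(l) < abs(best_l))) {
      best <- max(best, cc); best_l <- l
    }
  }
  best_l
}

# Brute-force SVM dual by dense active-set enumeration: every multiplier is
# assumed to be either free (interior), at 0, or at C; each consistent KKT
# system is solved and checked. Feasible candidates maximize the dual.
oracle_svm_dual <- function(K, y, C) {
  n <- length(y)
  Q <- (y %o% y) * K
  best <- NULL; best_obj <- -Inf
  states <- expand.grid(rep(list(0:2), n))  # 0 = at 0, 1 = free, 2 = at C
  for (s in seq_len(nrow(states))) {
    st <- as.integer(states[s, ])
    free <- which(st == 1L); atC <- which(st == 2L)
    alpha <- numeric(n); alpha[atC] <- C
    if (length(free)) {
      # KKT: Q[free,free] a_f + Q[free,atC] C 1 - 1 + b y_f = 0 ; y' a = 0
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      rhs <- c(rep(1, length(free)) - (if (length(atC))
        as.numeric(Q[free, atC, drop = FALSE] %*% rep(C, length(atC)))
        else 0),
        -C * sum(y[atC]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[free] <- sol[seq_along(free)]
      b <- sol[length(sol)]
    } else {
      if (abs(sum(alpha * y)) > 1e-9) next
      b <- NA_real_
    }
    if (any(alpha < -1e-9) || any(alpha > C + 1e-9)) next
    # KKT sign conditions at the bounds: grad_i = 1 - (Q alpha)_i - b y_i
    if (!is.na(b)) {
      g <- 1 - as.numeric(Q %*% alpha) - b * y
      if (any(g[st == 0L] > 1e-7)) next      # at 0 requires grad <= 0
      if (any(g[st == 2L] < -1e-7)) next     # at C requires grad >= 0
    }
    obj <- sum(alpha) - 0.5 * sum(alpha * (Q %*% alpha))
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      best <- list(alpha = alpha, obj = obj, b = b)
    }
  }
  best
}

# Small helper: a clearly separable 2-class 2-D feature set.
toy_two_class <- function(n_per = 10, gap = 4, seed = 42) {
  breathclass:::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
               matrix(rnorm(2 * n_per) + gap, ncol = 2))
    list(X = X, y = rep(c(-1, 1), each = n_per))
  })
}
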