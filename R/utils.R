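#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx convolve fft rnorm runif sd var cor
#' @importFrom utils read.csv head tail modifyList
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 7919 + p * 104729 + 12345) %% 2147483629
  as.integer(s) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) stopf("'%s' must be >= 0", name)
  invisible(x)
}
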