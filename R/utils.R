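#' @importFrom stats cov dist median prcomp predict pt rnorm runif sd
#'   t.test var rgamma setNames
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Run an expression under a temporary RNG seed
#'
#' Thin wrapper over [withr::with_seed()] so every stochastic operation in the
#' package is reproducible from an integer seed without disturbing the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Derive a stream-specific sub-seed from a base seed.  Lehmer-style mixing
## done in doubles (exact below 2^53) so the result stays inside the 32-bit
## integer range whatever the base seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483629)
}

## Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
cross_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

as_matrix_input <- function(x, arg = deparse(substitute(x))) {
  if (is_feature_table(x)) return(x$features)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("`%s` must be a numeric matrix or a feature_table", arg)
  }
  x
}
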