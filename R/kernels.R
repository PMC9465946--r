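#' RBF kernel with median-heuristic bandwidth
#'
#' Builds an RBF kernel specification `k(x, y) = exp(-gamma * ||x - y||^2)`
#' with `gamma = scale / (2 * M)`, where `M` is the median of all squared
#' pairwise Euclidean distances in the pooled evaluation set.  `scale = 1`
#' is the classic median heuristic (`sigma^2 = M`); scales of 0.1 and 10
#' probe the sensitivity of MMD to the bandwidth.
#'
#' @param X pooled n x d numeric matrix (or [feature_table()]), n >= 2.
#' @param scale positive bandwidth scale factor, conventionally 0.1, 1 or 10.
#' @return object of class `kernel_spec`: list with `M` (median squared
#'   pairwise distance), `scale`, `gamma`.
#' @export
median_heuristic <- function(X, scale = 1) {
  X <- as_matrix_input(X)
  if (nrow(X) < 2L) stopf("median heuristic needs at least 2 points")
  if (scale <= 0) stopf("`scale` must be > 0")
  M <- median(dist(X)^2)
  if (M <= 0) stopf("degenerate bandwidth: all points identical (median distance 0)")
  kernel_spec(gamma = scale / (2 * M), M = M, scale = scale)
}

#' @rdname median_heuristic
#' @param gamma positive RBF exponent coefficient.
#' @param M,scale optional provenance fields when `gamma` was derived from
#'   the median heuristic.
#' @export
kernel_spec <- function(gamma, M = NA_real_, scale = NA_real_) {
  if (!is.finite(gamma) || gamma <= 0) stopf("`gamma` must be a positive number")
  structure(list(M = M, scale = scale, gamma = gamma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> RBF gamma = %g (M = %g, scale = %g)\n",
              x$gamma, x$M, x$scale))
  invisible(x)
}

#' Evaluate the RBF kernel matrix between two point sets
#'
#' @param kernel a [kernel_spec()].
#' @param X,Y numeric matrices with matching column counts; `Y` defaults to `X`.
#' @return the |X| x |Y| kernel matrix.
#' @export
kernel_matrix <- function(kernel, X, Y = X) {
  stopifnot(inherits(kernel, "kernel_spec"))
  X <- as_matrix_input(X); Y <- as_matrix_input(Y)
  if (ncol(X) != ncol(Y)) stopf("dimension mismatch: %d vs %d columns", ncol(X), ncol(Y))
  exp(-kernel$gamma * cross_sqdist(X, Y))
}

mmd_result <- function(mmd2, estimator, n_source, n_target) {
  structure(list(mmd2 = mmd2, estimator = estimator,
                 n_source = n_source, n_target = n_target),
            class = "mmd_result")
}

#' @export
print.mmd_result <- function(x, ...) {
  cat(sprintf("<mmd_result> mmd2 = %g (%s estimator, n = %d/%d)\n",
              x$mmd2, x$estimator, x$n_source, x$n_target))
  invisible(x)
}

#' Squared maximum mean discrepancy, quadratic-time estimator
#'
#' The biased V-statistic: the two within-set kernel averages (diagonal
#' terms included) minus twice the cross-set average.  Always >= 0 up to
#' rounding for a PSD kernel.
#'
#' @param Xs,Xt source and target sample matrices (or [feature_table()]s)
#'   with equal column counts.
#' @param kernel a [kernel_spec()].
#' @return an `mmd_result` with `estimator = "quadratic"`.
#' @export
mmd2_quadratic <- function(Xs, Xt, kernel) {
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  if (nrow(Xs) < 1L || nrow(Xt) < 1L) stopf("both sample sets must be nonempty")
  if (ncol(Xs) != ncol(Xt)) stopf("dimension mismatch: %d vs %d columns", ncol(Xs), ncol(Xt))
  v <- mean(kernel_matrix(kernel, Xs)) + mean(kernel_matrix(kernel, Xt)) -
    2 * mean(kernel_matrix(kernel, Xs, Xt))
  mmd_result(v, "quadratic", nrow(Xs), nrow(Xt))
}

#' Squared maximum mean discrepancy, linear-time unbiased estimator
#'
#' Both sets are shuffled with `rng_seed`; if their sizes differ the larger
#' set is subsampled without replacement down to the smaller size, and an
#' odd size drops the final sample.  The estimator then averages, over
#' consecutive disjoint pairs (2i-1, 2i), the four kernel terms
#' `k(xs,xs') + k(xt,xt') - k(xs,xt') - k(xt,xs')`.  It touches each sample
#' once (linear time) and is unbiased for the population squared MMD.
#'
#' @inheritParams mmd2_quadratic
#' @param rng_seed integer seed controlling the shuffle/subsample.
#' @return an `mmd_result` with `estimator = "linear"`.
#' @export
mmd2_linear <- function(Xs, Xt, kernel, rng_seed = 1L) {
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  if (ncol(Xs) != ncol(Xt)) stopf("dimension mismatch: %d vs %d columns", ncol(Xs), ncol(Xt))
  n <- min(nrow(Xs), nrow(Xt))
  n <- n - n %% 2L
  if (n < 2L) stopf("insufficient data: need at least 2 samples per set after truncation")
  ## each set shuffled from the same seed, so identical sets get identical
  ## orderings (exact term cancellation when Xs == Xt)
  is_ <- with_seed(rng_seed, sample.int(nrow(Xs)))[seq_len(n)]
  it_ <- with_seed(rng_seed, sample.int(nrow(Xt)))[seq_len(n)]
  S <- Xs[is_, , drop = FALSE]
  T_ <- Xt[it_, , drop = FALSE]
  odd <- seq(1L, n, by = 2L)
  evn <- odd + 1L
  g <- kernel$gamma
  rbf_pair <- function(A, B) exp(-g * rowSums((A - B)^2))
  h <- rbf_pair(S[odd, , drop = FALSE], S[evn, , drop = FALSE]) +
    rbf_pair(T_[odd, , drop = FALSE], T_[evn, , drop = FALSE]) -
    rbf_pair(S[odd, , drop = FALSE], T_[evn, , drop = FALSE]) -
    rbf_pair(T_[odd, , drop = FALSE], S[evn, , drop = FALSE])
  mmd_result(mean(h), "linear", n, n)
}

#' Combined task + domain-confusion loss
#'
#' The deep-domain-confusion training objective: a task loss (typically
#' cross-entropy) plus `weight` times the squared MMD between source and
#' target activation batches at a chosen layer.
#'
#' @param task_loss nonnegative scalar task loss.
#' @param src_acts,tgt_acts activation batches (rows = samples).
#' @param kernel a [kernel_spec()].
#' @param weight nonnegative MMD penalty weight (lambda).
#' @param estimator `"linear"` (default, per-batch i.i.d. assumption) or
#'   `"quadratic"`.
#' @param rng_seed seed for the linear estimator's shuffle.
#' @return list with `total`, `task_loss`, `mmd2`, `weight`.
#' @export
ddc_loss <- function(task_loss, src_acts, tgt_acts, kernel, weight = 1,
                     estimator = c("linear", "quadratic"), rng_seed = 1L) {
  estimator <- match.arg(estimator)
  if (weight < 0) stopf("`weight` must be >= 0")
  if (task_loss < 0) stopf("`task_loss` must be >= 0")
  m <- if (estimator == "quadratic") {
    mmd2_quadratic(src_acts, tgt_acts, kernel)
  } else {
    mmd2_linear(src_acts, tgt_acts, kernel, rng_seed)
  }
  list(total = task_loss + weight * m$mmd2, task_loss = task_loss,
       mmd2 = m$mmd2, weight = weight)
}
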