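## Shared linear algebra: covariance estimation, PCA bases, and symmetric
## matrix functions used by the adaptation fits.

RANK_TOL <- 1e-10  # relative singular-value threshold for all rank decisions

#' Empirical covariance model
#'
#' Sample mean and covariance of the rows of `X`, with optional additive
#' ridge (`shrinkage * I`).  The covariance uses the unbiased 1/(n-1)
#' normalization for n >= 2; with a single sample the covariance is
#' `shrinkage * I`.  The numerical rank is the number of singular values
#' above `1e-10 * sigma_max`.
#'
#' @param X numeric n x d matrix (or [feature_table()]).
#' @param shrinkage nonnegative scalar added to the diagonal.
#' @return object of class `covariance_model`: list with `mean` (length d),
#'   `cov` (d x d), `rank`, `shrinkage`, `n`.
#' @export
empirical_covariance <- function(X, shrinkage = 0) {
  X <- as_matrix_input(X)
  if (ncol(X) == 0L) stopf("empty input: X has no columns")
  if (nrow(X) == 0L) stopf("empty input: X has no rows")
  if (shrinkage < 0) stopf("`shrinkage` must be >= 0")
  d <- ncol(X)
  mu <- colMeans(X)
  C <- if (nrow(X) >= 2L) {
    cov(X) + diag(shrinkage, d)
  } else {
    diag(shrinkage, d)
  }
  sv <- svd(C, nu = 0, nv = 0)$d
  rank <- if (max(sv) <= 0) 0L else sum(sv > RANK_TOL * max(sv))
  structure(
    list(mean = mu, cov = C, rank = rank, shrinkage = shrinkage, n = nrow(X)),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> d = %d, n = %d, rank = %d, shrinkage = %g\n",
              length(x$mean), x$n, x$rank, x$shrinkage))
  invisible(x)
}

#' Principal-component subspace basis
#'
#' Top-`k` principal directions of the (internally centered) rows of `X`,
#' ordered by decreasing explained variance.  If `k` exceeds the numerical
#' rank, the basis is truncated to the rank and flagged.  Each basis column
#' is sign-fixed so its largest-magnitude entry is positive, making the
#' decomposition deterministic.
#'
#' @param X numeric n x d matrix (or [feature_table()]), n >= 2.
#' @param k requested subspace dimension, k >= 1.
#' @return object of class `subspace_basis`: list with `basis` (d x k',
#'   orthonormal columns), `explained_variance` (length k', nonincreasing),
#'   `center` (length d), `truncated` (logical), `k_requested`.
#' @export
pca_basis <- function(X, k) {
  X <- as_matrix_input(X)
  if (nrow(X) < 2L) stopf("insufficient data: PCA needs n >= 2 samples")
  if (k < 1L) stopf("`k` must be >= 1")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  sv <- pc$sdev
  rank <- if (max(sv) <= 0) 0L else sum(sv > RANK_TOL * max(sv))
  if (rank == 0L) stopf("insufficient data: X has zero variance")
  truncated <- k > rank
  if (truncated) {
    warnf("requested k = %d exceeds numerical rank %d; truncating", k, rank)
    k <- rank
  }
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  ## sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(basis = V, explained_variance = pc$sdev[seq_len(k)]^2,
         center = pc$center, truncated = truncated, k_requested = k),
    class = "subspace_basis"
  )
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat(sprintf("<subspace_basis> d = %d, k = %d%s\n", nrow(x$basis),
              ncol(x$basis), if (x$truncated) " (truncated to rank)" else ""))
  invisible(x)
}

## Symmetric PSD matrix power via eigendecomposition, with the global
## relative rank threshold.  power = 0.5 gives the square root, -0.5 the
## pseudoinverse square root.  Returns list(mat, rank).
sym_psd_power <- function(C, power, rank_limit = Inf) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- RANK_TOL * max(abs(vals), 0)
  keep <- which(vals > tol)
  keep <- keep[seq_len(min(length(keep), rank_limit))]
  rank <- length(keep)
  if (rank == 0L) {
    return(list(mat = matrix(0, nrow(C), ncol(C)), rank = 0L))
  }
  U <- e$vectors[, keep, drop = FALSE]
  M <- U %*% (vals[keep]^power * t(U))
  list(mat = M, rank = rank)
}
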