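#' Fit a subspace alignment between source and target
#'
#' Both domains are projected onto their top-`k` PCA subspaces and the
#' source basis is aligned to the target basis with the matrix
#' `M = V_s' V_t`.  Source samples map to `x V_s M` and target samples to
#' `x V_t`, so both live in the k-dimensional target subspace.  `k` is
#' truncated (with a warning) to the smaller of the two numerical ranks.
#'
#' @param Xs,Xt source and target [feature_table()]s or matrices, each with
#'   at least 2 rows.
#' @param k subspace dimension; the conventional default is 100.
#' @return `linear_adaptation` with `kind = "subspace_align"`: subspace
#'   bases `V_s`, `V_t` ([pca_basis()] objects), aligner `M` (k x k), and a
#'   `truncated` flag.
#' @seealso [apply_subspace_alignment()], [tdas()]
#' @export
fit_subspace_alignment <- function(Xs, Xt, k = 100L) {
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  if (nrow(Xs) < 2L || nrow(Xt) < 2L) {
    stopf("insufficient data: subspace alignment needs n >= 2 on each side")
  }
  if (ncol(Xs) != ncol(Xt)) {
    stopf("dimension mismatch: source d = %d, target d = %d", ncol(Xs), ncol(Xt))
  }
  if (k < 1L) stopf("`k` must be >= 1")
  Vs_full <- suppressWarnings(pca_basis(Xs, min(k, ncol(Xs))))
  Vt_full <- suppressWarnings(pca_basis(Xt, min(k, ncol(Xt))))
  kk <- min(k, ncol(Vs_full$basis), ncol(Vt_full$basis))
  truncated <- kk < k
  if (truncated) warnf("k = %d truncated to %d (limited by data rank)", k, kk)
  keep <- function(b) {
    b$basis <- b$basis[, seq_len(kk), drop = FALSE]
    b$explained_variance <- b$explained_variance[seq_len(kk)]
    b
  }
  Vs <- keep(Vs_full); Vt <- keep(Vt_full)
  structure(
    list(kind = "subspace_align", V_s = Vs, V_t = Vt,
         M = crossprod(Vs$basis, Vt$basis), k = kk, truncated = truncated),
    class = "linear_adaptation"
  )
}

#' Project features through a fitted subspace alignment
#'
#' @param adapt a `linear_adaptation` of kind `"subspace_align"`.
#' @param X features to project (matrix or [feature_table()]).
#' @param role `"source"` (project onto the source basis then align with
#'   `M`) or `"target"` (project onto the target basis).
#' @return projected features of width `k`, same container type as `X`.
#' @details Centering is internal to the PCA basis fit only; samples are
#'   projected raw (`x V_s M` and `x V_t`), so a translation of one domain
#'   moves its subspace coordinates.  [tdas()] relies on this.
#' @export
apply_subspace_alignment <- function(adapt, X, role = c("source", "target")) {
  stopifnot(inherits(adapt, "linear_adaptation"))
  if (adapt$kind != "subspace_align") {
    stopf("`adapt` is of kind \"%s\", not \"subspace_align\"", adapt$kind)
  }
  role <- match.arg(role)
  Xm <- as_matrix_input(X)
  Z <- if (role == "source") {
    Xm %*% adapt$V_s$basis %*% adapt$M
  } else {
    Xm %*% adapt$V_t$basis
  }
  colnames(Z) <- paste0("sa_", seq_len(ncol(Z)) - 1L)
  if (is_feature_table(X)) {
    feature_table(Z, X$labels, X$domain, X$subject, X$recording)
  } else Z
}
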