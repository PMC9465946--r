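## Correlation alignment (CORAL) and its per-class variant.
##
## CORAL finds a linear map A on zero-meaned source features minimizing
## || A' C_s A - C_t ||_F^2.  The minimizer is A* = W R: first whiten the
## source with W = U_s S_s^(+1/2) U_s' (pseudoinverse square root of the
## source covariance), then recolour with R = U_t[1:r] S_t[1:r]^(1/2)
## U_t[1:r]', the square root of the target covariance truncated to
## r = min(rank C_s, rank C_t).

default_coral_shrinkage <- function(C) 1e-6 * sum(diag(C)) / ncol(C)

#' Fit a CORAL transform
#'
#' Learns the closed-form correlation-alignment matrix that maps zero-meaned
#' source features so their covariance matches the target covariance.  A
#' small ridge (`1e-6 * trace(C)/d` per side by default) keeps downstream
#' inverses stable; set `shrinkage = 0` to exercise the pure
#' pseudoinverse/truncation path on rank-deficient data.
#'
#' @param Xs,Xt source and target [feature_table()]s (or plain matrices)
#'   with equal feature dimension.
#' @param shrinkage ridge added to each covariance; `NULL` (default) uses
#'   `1e-6 * trace(C)/d` computed per side.
#' @param recenter `"none"` (transformed source left zero-meaned, the Eq.-1
#'   setting) or `"target"` (add the target mean back).
#' @return object of class `linear_adaptation` with `kind = "coral"`:
#'   the matrix `A`, the covariance models used, both means, and the rank
#'   `r` used for the target truncation.
#' @seealso [apply_coral()], [fit_per_class_coral()]
#' @export
fit_coral <- function(Xs, Xt, shrinkage = NULL, recenter = c("none", "target")) {
  recenter <- match.arg(recenter)
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  if (ncol(Xs) != ncol(Xt)) {
    stopf("dimension mismatch: source d = %d, target d = %d", ncol(Xs), ncol(Xt))
  }
  cs0 <- empirical_covariance(Xs, 0)
  ct0 <- empirical_covariance(Xt, 0)
  sh_s <- shrinkage %||% default_coral_shrinkage(cs0$cov)
  sh_t <- shrinkage %||% default_coral_shrinkage(ct0$cov)
  cs <- empirical_covariance(Xs, sh_s)
  ct <- empirical_covariance(Xt, sh_t)
  r <- min(cs$rank, ct$rank)
  W <- sym_psd_power(cs$cov, -0.5)             # source whitener (pinv sqrt)
  R <- sym_psd_power(ct$cov, 0.5, rank_limit = r)  # target recolourer, top r
  structure(
    list(kind = "coral", A = W$mat %*% R$mat,
         mean_s = cs$mean, mean_t = ct$mean,
         cov_s = cs, cov_t = ct, rank_used = r, recenter = recenter),
    class = "linear_adaptation"
  )
}

#' Apply a fitted CORAL transform to source features
#'
#' Rows are mapped as `(x - mean_s) %*% A`, then the target mean is added
#' back when the fit used `recenter = "target"`.  Labels and IDs are
#' carried through unchanged.
#'
#' @param adapt a `linear_adaptation` of kind `"coral"` from [fit_coral()].
#' @param Xs source [feature_table()] (or matrix) to transform.
#' @return an object of the same type as `Xs` with transformed features.
#' @export
apply_coral <- function(adapt, Xs) {
  stopifnot(inherits(adapt, "linear_adaptation"))
  if (adapt$kind != "coral") stopf("`adapt` is of kind \"%s\", not \"coral\"", adapt$kind)
  X <- as_matrix_input(Xs)
  if (ncol(X) != length(adapt$mean_s)) {
    stopf("dimension mismatch: transform expects d = %d", length(adapt$mean_s))
  }
  Z <- sweep(X, 2L, adapt$mean_s) %*% adapt$A
  if (adapt$recenter == "target") Z <- sweep(Z, 2L, adapt$mean_t, "+")
  colnames(Z) <- colnames(X)
  if (is_feature_table(Xs)) {
    feature_table(Z, Xs$labels, Xs$domain, Xs$subject, Xs$recording)
  } else Z
}

#' Fit Per-Class CORAL
#'
#' Fits one CORAL matrix per class, aligning the covariance of source
#' samples in class i with the covariance of target samples in class i.
#' Classes missing from either side, or with fewer than `min_class_n`
#' samples on either side, fall back to the global CORAL transform; the
#' fallback classes are recorded in the result.
#'
#' @inheritParams fit_coral
#' @param min_class_n minimum per-side class size for a class-specific fit;
#'   default `d + 2` (below this the class covariance is singular).
#' @param global_fallback if `FALSE`, fitting errors when no class meets the
#'   threshold instead of returning the global transform everywhere.
#' @return `linear_adaptation` with `kind = "per_class_coral"`: a named list
#'   `per_class` of CORAL fits, the `global` fit, and `fallback_classes`.
#' @export
fit_per_class_coral <- function(Xs, Xt, shrinkage = NULL,
                                recenter = c("none", "target"),
                                min_class_n = NULL, global_fallback = TRUE) {
  recenter <- match.arg(recenter)
  if (!is_feature_table(Xs) || !is_feature_table(Xt)) {
    stopf("Per-Class CORAL needs labeled feature_table inputs")
  }
  d <- ncol(Xs$features)
  min_class_n <- min_class_n %||% (d + 2L)
  classes <- sort(unique(Xs$labels))
  global <- fit_coral(Xs, Xt, shrinkage, recenter)
  per_class <- list()
  fallback <- character()
  for (cl in classes) {
    is_s <- Xs$labels == cl
    is_t <- Xt$labels == cl
    if (sum(is_s) >= min_class_n && sum(is_t) >= min_class_n) {
      per_class[[cl]] <- fit_coral(Xs$features[is_s, , drop = FALSE],
                                   Xt$features[is_t, , drop = FALSE],
                                   shrinkage, recenter)
    } else {
      fallback <- c(fallback, cl)
    }
  }
  if (length(per_class) == 0L && !global_fallback) {
    stopf("no class has >= %d samples on both sides and global fallback is disabled",
          min_class_n)
  }
  structure(
    list(kind = "per_class_coral", per_class = per_class, global = global,
         fallback_classes = fallback, min_class_n = min_class_n,
         recenter = recenter),
    class = "linear_adaptation"
  )
}

#' Apply a fitted Per-Class CORAL transform
#'
#' Each source sample is transformed with its class's matrix (class-specific
#' centering and, under `recenter = "target"`, the matching target class
#' mean); samples of fallback classes use the global transform.
#'
#' @param adapt a `linear_adaptation` of kind `"per_class_coral"`.
#' @param Xs labeled source [feature_table()].
#' @return transformed [feature_table()].
#' @export
apply_per_class_coral <- function(adapt, Xs) {
  stopifnot(inherits(adapt, "linear_adaptation"))
  if (adapt$kind != "per_class_coral") {
    stopf("`adapt` is of kind \"%s\", not \"per_class_coral\"", adapt$kind)
  }
  if (!is_feature_table(Xs)) stopf("Per-Class CORAL transforms labeled feature_tables")
  Z <- Xs$features
  for (cl in unique(Xs$labels)) {
    idx <- Xs$labels == cl
    fit <- adapt$per_class[[cl]] %||% adapt$global
    Z[idx, ] <- apply_coral(fit, Xs$features[idx, , drop = FALSE])
  }
  feature_table(Z, Xs$labels, Xs$domain, Xs$subject, Xs$recording)
}

#' @export
print.linear_adaptation <- function(x, ...) {
  cat(sprintf("<linear_adaptation> kind = %s\n", x$kind))
  if (x$kind == "coral") {
    cat(sprintf("  d = %d, rank used r = %d, recenter = %s\n",
                nrow(x$A), x$rank_used, x$recenter))
  } else if (x$kind == "per_class_coral") {
    cat(sprintf("  %d class-specific fits, fallback classes: %s\n",
                length(x$per_class),
                if (length(x$fallback_classes)) paste(x$fallback_classes, collapse = ", ")
                else "none"))
  } else if (x$kind == "subspace_align") {
    cat(sprintf("  d = %d -> k = %d%s\n", nrow(x$V_s$basis), ncol(x$V_s$basis),
                if (x$truncated) " (truncated)" else ""))
  }
  invisible(x)
}
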