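# Independent brute-force oracles used to pin expected values.  Each is a
# deliberately naive double-loop implementation, kept separate from the
# package's vectorized code paths.

oracle_covariance <- function(X) {
  n <- nrow(X); d <- ncol(X)
  m <- colMeans(X)
  C <- matrix(0, d, d)
  for (i in seq_len(n)) {
    v <- X[i, ] - m
    C <- C + outer(v, v)
  }
  C / (n - 1)
}

oracle_rbf <- function(x, y, gamma) exp(-gamma * sum((x - y)^2))

oracle_mmd2_quadratic <- function(Xs, Xt, gamma) {
  ns <- nrow(Xs); nt <- nrow(Xt)
  s1 <- 0; for (i in seq_len(ns)) for (j in seq_len(ns))
    s1 <- s1 + oracle_rbf(Xs[i, ], Xs[j, ], gamma)
  s2 <- 0; for (i in seq_len(nt)) for (j in seq_len(nt))
    s2 <- s2 + oracle_rbf(Xt[i, ], Xt[j, ], gamma)
  s3 <- 0; for (i in seq_len(ns)) for (j in seq_len(nt))
    s3 <- s3 + oracle_rbf(Xs[i, ], Xt[j, ], gamma)
  s1 / ns^2 + s2 / nt^2 - 2 * s3 / (ns * nt)
}

oracle_h_score <- function(X, y) {
  n <- nrow(X)
  mu <- colMeans(X)
  ct <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) ct <- ct + outer(X[i, ] - mu, X[i, ] - mu)
  ct <- ct / n
  cb <- matrix(0, ncol(X), ncol(X))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    mc <- colMeans(X[idx, , drop = FALSE])
    cb <- cb + (length(idx) / n) * outer(mc - mu, mc - mu)
  }
  sum(diag(MASS::ginv(ct) %*% cb))
}

oracle_hypothesis_margin <- function(Xs, Xt) {
  U <- rbind(Xs, Xt)
  grp <- c(rep(1L, nrow(Xs)), rep(2L, nrow(Xt)))
  n <- nrow(U)
  margins <- numeric(n)
  for (i in seq_len(n)) {
    hit <- miss <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((U[i, ] - U[j, ])^2))
      if (grp[j] == grp[i]) hit <- min(hit, dij) else miss <- min(miss, dij)
    }
    margins[i] <- 0.5 * (miss - hit)
  }
  mean(margins)
}

# TDAS oracle with its own PCA (prcomp rotations directly; the similarity is
# invariant to per-column sign flips, so no sign convention is needed).
oracle_tdas <- function(Xs, Xt, k, eps_scale) {
  Vs <- prcomp(Xs)$rotation[, seq_len(k), drop = FALSE]
  Vt <- prcomp(Xt)$rotation[, seq_len(k), drop = FALSE]
  M <- t(Vs) %*% Vt
  m <- median(as.numeric(dist(Xt)))
  eps <- eps_scale * m
  total <- 0
  for (i in seq_len(nrow(Xs))) {
    ps <- drop(Xs[i, ] %*% Vs %*% M)
    cnt <- 0
    for (j in seq_len(nrow(Xt))) {
      pt_ <- drop(Xt[j, ] %*% Vt)
      if (sum(ps * pt_) >= eps) cnt <- cnt + 1
    }
    total <- total + cnt
  }
  total / nrow(Xs)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

oracle_kappa <- function(y_true, y_pred) {
  lv <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  conf <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(n)) conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  (po - pe) / (1 - pe)
}
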