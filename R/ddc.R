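## Deep-domain-confusion reference trainer: a one-hidden-layer softmax
## network trained jointly on labeled source and target batches with an MMD
## penalty between the source and target hidden activations.  Gradients,
## including the RBF-MMD term, are computed analytically; optimization is
## Adam.  The kernel bandwidth is re-derived per batch from the pooled
## hidden activations (median heuristic) and treated as a constant with
## respect to the gradient.

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## gradient of the quadratic V-statistic MMD^2 w.r.t. source/target
## activation rows, for k(x,y) = exp(-g ||x-y||^2)
mmd2_quadratic_grad <- function(Hs, Ht, g) {
  ns <- nrow(Hs); nt <- nrow(Ht)
  Kss <- exp(-g * cross_sqdist(Hs, Hs))
  Ktt <- exp(-g * cross_sqdist(Ht, Ht))
  Kst <- exp(-g * cross_sqdist(Hs, Ht))
  mmd2 <- mean(Kss) + mean(Ktt) - 2 * mean(Kst)
  dHs <- (-4 * g / ns^2) * (rowSums(Kss) * Hs - Kss %*% Hs) +
    (4 * g / (ns * nt)) * (rowSums(Kst) * Hs - Kst %*% Ht)
  dHt <- (-4 * g / nt^2) * (rowSums(Ktt) * Ht - Ktt %*% Ht) +
    (4 * g / (ns * nt)) * (colSums(Kst) * Ht - crossprod(Kst, Hs))
  list(mmd2 = mmd2, dHs = dHs, dHt = dHt)
}

## gradient of the linear-time estimator over consecutive disjoint pairs
mmd2_linear_grad <- function(Hs, Ht, g) {
  n <- min(nrow(Hs), nrow(Ht))
  n <- n - n %% 2L
  if (n < 2L) return(NULL)
  odd <- seq(1L, n, by = 2L); evn <- odd + 1L
  so <- Hs[odd, , drop = FALSE]; se <- Hs[evn, , drop = FALSE]
  to <- Ht[odd, , drop = FALSE]; te <- Ht[evn, , drop = FALSE]
  kf <- function(A, B) exp(-g * rowSums((A - B)^2))
  k1 <- kf(so, se); k2 <- kf(to, te); k3 <- kf(so, te); k4 <- kf(to, se)
  q <- n / 2
  mmd2 <- mean(k1 + k2 - k3 - k4)
  dHs <- matrix(0, nrow(Hs), ncol(Hs))
  dHt <- matrix(0, nrow(Ht), ncol(Ht))
  c2g <- -2 * g / q
  dHs[odd, ] <- c2g * ((so - se) * k1 - (so - te) * k3)
  dHs[evn, ] <- c2g * ((se - so) * k1 - (se - to) * k4)
  dHt[odd, ] <- c2g * ((to - te) * k2 - (to - se) * k4)
  dHt[evn, ] <- c2g * ((te - to) * k2 - (te - so) * k3)
  list(mmd2 = mmd2, dHs = dHs, dHt = dHt)
}

ddc_forward <- function(W, X) {
  H <- tanh(sweep(X %*% W$W1, 2L, W$b1, "+"))
  Z <- sweep(H %*% W$W2, 2L, W$b2, "+")
  list(H = H, P = softmax_rows(Z))
}

#' Reference trainer with a domain-confusion (MMD) penalty
#'
#' Trains a small one-hidden-layer softmax network simultaneously on labeled
#' source and target samples.  Each step draws paired source/target
#' mini-batches; the loss is the pooled cross-entropy plus
#' `lambda * MMD^2` between the source-batch and target-batch hidden
#' activations, so the network is pushed toward domain-invariant hidden
#' features.  With `lambda = 0` this reduces to plain supervised training
#' on the pooled data under the same batch schedule.
#'
#' @param Xs,Xt source/target features (matrix or [feature_table()]).
#' @param ys,yt class labels (taken from the feature tables when `NULL`).
#' @param hidden_width hidden-layer width.
#' @param lambda nonnegative MMD penalty weight.
#' @param epochs training epochs.
#' @param batch_size per-domain mini-batch size.
#' @param lr Adam learning rate (default 0.001).
#' @param l2 L2 weight decay.
#' @param estimator MMD estimator used inside batches: `"linear"` (default;
#'   pairs consecutive samples of the shuffled batch) or `"quadratic"`.
#' @param seed integer seed (initialization and batch shuffles).
#' @return object of class `ddc_model`: weights, `classes`, per-epoch
#'   `trace` (`task_loss`, `mmd2`), and `final_mmd2`, the quadratic-estimator
#'   MMD of the hidden activations over the full source/target sets after
#'   training (median-heuristic bandwidth on the pooled activations).
#' @export
ddc_reference_train <- function(Xs, ys = NULL, Xt, yt = NULL,
                                hidden_width = 16L, lambda = 1,
                                epochs = 30L, batch_size = 64L,
                                lr = 0.001, l2 = 10^-6.9,
                                estimator = c("linear", "quadratic"),
                                seed = 1L) {
  estimator <- match.arg(estimator)
  if (lambda < 0) stopf("`lambda` must be >= 0")
  if (is_feature_table(Xs) && is.null(ys)) ys <- Xs$labels
  if (is_feature_table(Xt) && is.null(yt)) yt <- Xt$labels
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  if (nrow(Xt) == 0L || is.null(yt)) stopf("target training split must be nonempty and labeled")
  if (ncol(Xs) != ncol(Xt)) stopf("dimension mismatch between source and target features")
  classes <- sort(unique(c(as.character(ys), as.character(yt))))
  K <- length(classes)
  d <- ncol(Xs)
  Ys <- diag(K)[match(as.character(ys), classes), , drop = FALSE]
  Yt <- diag(K)[match(as.character(yt), classes), , drop = FALSE]

  W <- with_seed(seed, list(
    W1 = matrix(rnorm(d * hidden_width, sd = 1 / sqrt(d)), d, hidden_width),
    b1 = numeric(hidden_width),
    W2 = matrix(rnorm(hidden_width * K, sd = 1 / sqrt(hidden_width)), hidden_width, K),
    b2 = numeric(K)
  ))
  adam <- list(m = lapply(W, function(w) w * 0), v = lapply(W, function(w) w * 0), t = 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8

  steps_per_epoch <- max(1L, floor(min(nrow(Xs), nrow(Xt)) / batch_size))
  trace <- data.frame(epoch = integer(), task_loss = numeric(), mmd2 = numeric())

  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), list(s = sample.int(nrow(Xs)),
                                                 t = sample.int(nrow(Xt))))
    ep_task <- ep_mmd <- 0
    for (st in seq_len(steps_per_epoch)) {
      pick <- function(o, n) o[((st - 1L) * batch_size) %% n + seq_len(min(batch_size, n))]
      si <- pick(ord$s, nrow(Xs)); si <- si[!is.na(si)]
      ti <- pick(ord$t, nrow(Xt)); ti <- ti[!is.na(ti)]
      m <- min(length(si), length(ti))
      si <- si[seq_len(m)]; ti <- ti[seq_len(m)]
      Xb <- rbind(Xs[si, , drop = FALSE], Xt[ti, , drop = FALSE])
      Yb <- rbind(Ys[si, , drop = FALSE], Yt[ti, , drop = FALSE])
      fw <- ddc_forward(W, Xb)
      nb <- nrow(Xb)
      task <- -mean(log(pmax(rowSums(fw$P * Yb), 1e-300)))
      dZ <- (fw$P - Yb) / nb
      dH <- dZ %*% t(W$W2)
      mmd2 <- 0
      if (lambda > 0 && m >= 2L) {
        Hs <- fw$H[seq_len(m), , drop = FALSE]
        Ht <- fw$H[m + seq_len(m), , drop = FALSE]
        Msq <- median(dist(rbind(Hs, Ht))^2)
        if (Msq > 0) {
          g <- 1 / (2 * Msq)
          gr <- if (estimator == "quadratic") mmd2_quadratic_grad(Hs, Ht, g)
                else mmd2_linear_grad(Hs, Ht, g)
          if (!is.null(gr)) {
            mmd2 <- gr$mmd2
            dH[seq_len(m), ] <- dH[seq_len(m), ] + lambda * gr$dHs
            dH[m + seq_len(m), ] <- dH[m + seq_len(m), ] + lambda * gr$dHt
          }
        }
      }
      dA <- dH * (1 - fw$H^2)
      grad <- list(W1 = crossprod(Xb, dA) + l2 * W$W1,
                   b1 = colSums(dA),
                   W2 = crossprod(fw$H, dZ) + l2 * W$W2,
                   b2 = colSums(dZ))
      adam$t <- adam$t + 1
      for (nm in names(W)) {
        adam$m[[nm]] <- b1a * adam$m[[nm]] + (1 - b1a) * grad[[nm]]
        adam$v[[nm]] <- b2a * adam$v[[nm]] + (1 - b2a) * grad[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - b1a^adam$t)
        vhat <- adam$v[[nm]] / (1 - b2a^adam$t)
        W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_task <- ep_task + task
      ep_mmd <- ep_mmd + mmd2
    }
    trace <- rbind(trace, data.frame(epoch = ep,
                                     task_loss = ep_task / steps_per_epoch,
                                     mmd2 = ep_mmd / steps_per_epoch))
  }

  Hs_all <- ddc_forward(W, Xs)$H
  Ht_all <- ddc_forward(W, Xt)$H
  final_mmd2 <- tryCatch({
    ks <- median_heuristic(rbind(Hs_all, Ht_all))
    mmd2_quadratic(Hs_all, Ht_all, ks)$mmd2
  }, error = function(e) 0)

  structure(
    list(weights = W, classes = classes, trace = trace,
         final_mmd2 = final_mmd2, lambda = lambda, estimator = estimator,
         hidden_width = hidden_width, seed = seed, d = d),
    class = "ddc_model"
  )
}

#' @export
print.ddc_model <- function(x, ...) {
  cat(sprintf("<ddc_model> %d-%d-%d network, lambda = %g, final hidden MMD^2 = %.4g\n",
              x$d, x$hidden_width, length(x$classes), x$lambda, x$final_mmd2))
  invisible(x)
}

#' @export
predict.ddc_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_matrix_input(newdata)
  if (ncol(X) != object$d) stopf("newdata has d = %d, model expects %d", ncol(X), object$d)
  P <- ddc_forward(object$weights, X)$P
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}
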