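#' Train the classification head
#'
#' The "head" standing in for the single dense layer adjacent to the output
#' of a frozen feature extractor: a multinomial logistic classifier fitted
#' on feature activations.  Fitting is delegated to [nnet::multinom()] with
#' L2 weight decay; the default decay of `10^-6.9` matches the regularization
#' weight used when pre-training the reference network.
#'
#' @param X n x d feature matrix or [feature_table()].
#' @param y length-n class labels (taken from `X` when it is a feature
#'   table and `y` is `NULL`).
#' @param l2 L2 regularization (weight-decay) strength.
#' @param max_iter optimizer iteration cap.
#' @param seed integer seed (weight initialization), making fits
#'   deterministic.
#' @return object of class `head_classifier` with the fitted model,
#'   `classes`, and training metadata.
#' @export
train_head <- function(X, y = NULL, l2 = 10^-6.9, max_iter = 200L, seed = 1L) {
  if (is_feature_table(X) && is.null(y)) y <- X$labels
  X <- as_matrix_input(X)
  if (is.null(y) || length(y) != nrow(X)) stopf("`y` must supply one label per row")
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stopf("degenerate labels: need >= 2 classes, got %d", nlevels(y))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- y
  fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df, decay = l2,
                                        maxit = max_iter, trace = FALSE,
                                        MaxNWts = 1e5))
  structure(
    list(fit = fit, classes = levels(y), d = ncol(X),
         l2 = l2, max_iter = max_iter, seed = seed,
         final_loss = fit$value, converged = fit$convergence == 0),
    class = "head_classifier"
  )
}

#' @export
print.head_classifier <- function(x, ...) {
  cat(sprintf("<head_classifier> %d features -> %d classes (loss %.4f%s)\n",
              x$d, length(x$classes), x$final_loss,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Predict classes or posteriors from a head classifier
#'
#' @param object a `head_classifier`.
#' @param newdata feature matrix or [feature_table()].
#' @param type `"class"` for hard labels, `"prob"` for a row-stochastic
#'   posterior matrix with one column per training class.
#' @param ... unused.
#' @export
predict.head_classifier <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_matrix_input(newdata)
  if (ncol(X) != object$d) stopf("newdata has d = %d, model expects %d", ncol(X), object$d)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  P <- predict(object$fit, newdata = df, type = "probs")
  if (is.null(dim(P))) {   # binary case: multinom returns P(class 2)
    P <- cbind(1 - P, P)
  }
  P <- matrix(as.numeric(P), nrow = nrow(X), dimnames = list(NULL, object$classes))
  if (type == "prob") return(P / rowSums(P))
  object$classes[max.col(P, ties.method = "first")]
}

head_accuracy <- function(model, X, y) {
  mean(predict(model, X, type = "class") == as.character(y))
}
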