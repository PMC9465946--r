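## JSON serialization of fitted linear adaptations (matrices as nested
## arrays, metadata verbatim).

adaptation_payload <- function(x) {
  if (x$kind == "coral") {
    list(kind = "coral", A = x$A, mean_s = x$mean_s, mean_t = x$mean_t,
         cov_s = list(mean = x$cov_s$mean, cov = x$cov_s$cov,
                      rank = x$cov_s$rank, shrinkage = x$cov_s$shrinkage,
                      n = x$cov_s$n),
         cov_t = list(mean = x$cov_t$mean, cov = x$cov_t$cov,
                      rank = x$cov_t$rank, shrinkage = x$cov_t$shrinkage,
                      n = x$cov_t$n),
         rank_used = x$rank_used, recenter = x$recenter)
  } else if (x$kind == "per_class_coral") {
    list(kind = "per_class_coral",
         per_class = lapply(x$per_class, adaptation_payload),
         global = adaptation_payload(x$global),
         fallback_classes = x$fallback_classes,
         min_class_n = x$min_class_n, recenter = x$recenter)
  } else if (x$kind == "subspace_align") {
    list(kind = "subspace_align",
         V_s = list(basis = x$V_s$basis,
                    explained_variance = x$V_s$explained_variance,
                    center = x$V_s$center),
         V_t = list(basis = x$V_t$basis,
                    explained_variance = x$V_t$explained_variance,
                    center = x$V_t$center),
         M = x$M, k = x$k, truncated = x$truncated)
  } else stopf("unknown adaptation kind \"%s\"", x$kind)
}

#' Write and read fitted adaptations as JSON
#'
#' @param adapt a `linear_adaptation` from [fit_coral()],
#'   [fit_per_class_coral()] or [fit_subspace_alignment()].
#' @param path JSON path.
#' @return `read_adaptation()` returns the reconstructed
#'   `linear_adaptation`; matrices survive the round trip at full precision.
#' @export
write_adaptation <- function(adapt, path) {
  stopifnot(inherits(adapt, "linear_adaptation"))
  jsonlite::write_json(adaptation_payload(adapt), path, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

rebuild_cov <- function(p) {
  structure(list(mean = as.numeric(p$mean), cov = as.matrix(p$cov),
                 rank = as.integer(p$rank), shrinkage = p$shrinkage,
                 n = as.integer(p$n)), class = "covariance_model")
}

rebuild_adaptation <- function(p) {
  if (p$kind == "coral") {
    structure(list(kind = "coral", A = as.matrix(p$A),
                   mean_s = as.numeric(p$mean_s), mean_t = as.numeric(p$mean_t),
                   cov_s = rebuild_cov(p$cov_s), cov_t = rebuild_cov(p$cov_t),
                   rank_used = as.integer(p$rank_used), recenter = p$recenter),
              class = "linear_adaptation")
  } else if (p$kind == "per_class_coral") {
    structure(list(kind = "per_class_coral",
                   per_class = lapply(p$per_class, rebuild_adaptation),
                   global = rebuild_adaptation(p$global),
                   fallback_classes = as.character(unlist(p$fallback_classes)),
                   min_class_n = as.integer(p$min_class_n), recenter = p$recenter),
              class = "linear_adaptation")
  } else if (p$kind == "subspace_align") {
    rb <- function(b) structure(
      list(basis = as.matrix(b$basis),
           explained_variance = as.numeric(b$explained_variance),
           center = as.numeric(b$center), truncated = FALSE,
           k_requested = ncol(as.matrix(b$basis))),
      class = "subspace_basis")
    structure(list(kind = "subspace_align", V_s = rb(p$V_s), V_t = rb(p$V_t),
                   M = as.matrix(p$M), k = as.integer(p$k),
                   truncated = isTRUE(p$truncated)),
              class = "linear_adaptation")
  } else stopf("unknown adaptation kind in file")
}

#' @rdname write_adaptation
#' @export
read_adaptation <- function(path) {
  rebuild_adaptation(jsonlite::read_json(path, simplifyVector = TRUE))
}
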