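#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with the
#' expected agreement `p_e` from the product of the two sets of marginal
#' class frequencies.  When `p_e = 1` (both raters constant on the same
#' class) kappa is 1 if agreement is perfect and undefined otherwise.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return scalar kappa.
#' @export
cohens_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("length mismatch: %d vs %d", length(y_true), length(y_pred))
  }
  if (length(y_true) < 1L) stopf("need at least one sample")
  lv <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  a <- factor(as.character(y_true), levels = lv)
  b <- factor(as.character(y_pred), levels = lv)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (abs(1 - p_e) < 1e-15) {
    if (p_o == 1) return(1)
    stopf("undefined kappa: expected agreement is 1 but observed agreement is %.3f", p_o)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks are used for ties; the two-sided p-value comes from the
#' usual `t = r * sqrt((n - 2) / (1 - r^2))` approximation on n - 2 degrees
#' of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  n <- length(x)
  if (n < 3L) stopf("need n >= 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    stopf("undefined correlation: zero variance in ranks")
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Paired t-test wrapper
#'
#' Standard two-sided paired t-test on the differences `a - b`, erroring
#' explicitly (rather than returning 0) when the differences have zero
#' variance.
#'
#' @param a,b equal-length numeric vectors, n >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch: %d vs %d", length(a), length(b))
  if (length(a) < 2L) stopf("need n >= 2 pairs")
  d <- a - b
  if (sd(d) == 0) stopf("undefined test: paired differences have zero variance")
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Tally the winning algorithm per fold
#'
#' For every fold the accuracy-maximal algorithm earns the win; exact ties
#' split the win equally.  Fractions are over folds and sum to 1.
#'
#' @param folds data.frame with columns `fold`, `algorithm`, `accuracy`;
#'   every fold must score every algorithm.
#' @return named numeric vector of win fractions per algorithm.
#' @export
tally_best <- function(folds) {
  stopifnot(all(c("fold", "algorithm", "accuracy") %in% names(folds)))
  algos <- sort(unique(folds$algorithm))
  ids <- unique(folds$fold)
  wins <- setNames(numeric(length(algos)), algos)
  for (f in ids) {
    sub <- folds[folds$fold == f, ]
    if (!setequal(sub$algorithm, algos) || nrow(sub) != length(algos)) {
      stopf("fold %s does not score every algorithm exactly once", f)
    }
    best <- sub$algorithm[sub$accuracy == max(sub$accuracy)]
    wins[best] <- wins[best] + 1 / length(best)
  }
  wins / length(ids)
}

## Balance the source against the target: first recording per subject only,
## then every nth recording with n = floor(#source recordings / #target
## recordings), in recording order.
balance_source_recordings <- function(source, n_target_recordings) {
  stopifnot(is_feature_table(source))
  key <- paste(source$subject, source$recording)
  first_rec <- tapply(source$recording, source$subject,
                      function(r) sort(unique(r))[1L])
  keep_key <- paste(names(first_rec), first_rec)
  idx_first <- key %in% keep_key
  recs <- sort(unique(key[idx_first]))
  step <- max(1L, floor(length(recs) / max(1L, n_target_recordings)))
  chosen <- recs[seq(1L, length(recs), by = step)]
  subset_rows(source, which(idx_first & key %in% chosen))
}

fit_and_eval <- function(algorithm, src_bal, tgt_train, tgt_test,
                         head_cfg, seed) {
  l2 <- head_cfg$l2 %||% 10^-6.9
  max_iter <- head_cfg$max_iter %||% 200L
  k <- head_cfg$subspace_k %||% 100L
  test_y <- tgt_test$labels
  pred <- switch(
    algorithm,
    head_retrain = {
      hd <- train_head(tgt_train, l2 = l2, max_iter = max_iter, seed = seed)
      predict(hd, tgt_test, type = "class")
    },
    coral = {
      ad <- fit_coral(src_bal, tgt_train, recenter = "target")
      pooled_X <- rbind(apply_coral(ad, src_bal)$features, tgt_train$features)
      pooled_y <- c(src_bal$labels, tgt_train$labels)
      hd <- train_head(pooled_X, pooled_y, l2 = l2, max_iter = max_iter, seed = seed)
      predict(hd, tgt_test, type = "class")
    },
    per_class_coral = {
      ad <- fit_per_class_coral(src_bal, tgt_train, recenter = "target")
      pooled_X <- rbind(apply_per_class_coral(ad, src_bal)$features,
                        tgt_train$features)
      pooled_y <- c(src_bal$labels, tgt_train$labels)
      hd <- train_head(pooled_X, pooled_y, l2 = l2, max_iter = max_iter, seed = seed)
      predict(hd, tgt_test, type = "class")
    },
    subspace_align = {
      ad <- suppressWarnings(fit_subspace_alignment(src_bal, tgt_train, k))
      pooled_X <- rbind(apply_subspace_alignment(ad, src_bal, "source")$features,
                        apply_subspace_alignment(ad, tgt_train, "target")$features)
      pooled_y <- c(src_bal$labels, tgt_train$labels)
      hd <- train_head(pooled_X, pooled_y, l2 = l2, max_iter = max_iter, seed = seed)
      predict(hd, apply_subspace_alignment(ad, tgt_test, "target"), type = "class")
    },
    ddc = {
      md <- ddc_reference_train(
        src_bal, NULL, tgt_train, NULL,
        hidden_width = head_cfg$hidden_width %||% 16L,
        lambda = head_cfg$lambda %||% 1,
        epochs = head_cfg$epochs %||% 20L,
        seed = seed)
      predict(md, tgt_test, type = "class")
    },
    stopf("unknown algorithm \"%s\"", algorithm)
  )
  list(accuracy = mean(pred == test_y),
       kappa = cohens_kappa(test_y, pred))
}

#' Leave-one-subject-out benchmark of adaptation algorithms
#'
#' Runs the full evaluation protocol on a labeled source/target pair: for
#' each held-out target subject, every algorithm is fitted on the (balanced)
#' source plus the remaining target subjects and scored on the held-out
#' subject (accuracy and Cohen's kappa).  Transferability measures are
#' computed per fold on the training-portion data only — never on the
#' held-out subject.  The result aggregates per-algorithm summaries,
#' best-algorithm tallies, paired t-tests against the head-retraining
#' baseline, and Spearman correlations of every measure with fold accuracy.
#'
#' @param source,target labeled [feature_table()]s; the target needs at
#'   least 2 subjects.
#' @param algorithms subset of `"head_retrain"`, `"coral"`,
#'   `"per_class_coral"`, `"subspace_align"`, `"ddc"`.
#' @param measures measure names passed to [compute_measures()]; `NULL`
#'   skips measures.
#' @param head_cfg list of knobs: `l2`, `max_iter`, `subspace_k`,
#'   `hidden_width`, `lambda`, `epochs`, `downsample`.
#' @param seed integer seed; all per-fold randomness derives from it.
#' @return object of class `benchmark_result` with data.frames `folds`,
#'   `measures`, `summary`, `tallies`, `ttests`, `correlations`.
#' @export
loso_benchmark <- function(source, target,
                           algorithms = c("head_retrain", "coral"),
                           measures = c("h_score", "tdas", "mmd"),
                           head_cfg = list(), seed = 1L) {
  stopifnot(is_feature_table(source), is_feature_table(target))
  valid <- c("head_retrain", "coral", "per_class_coral", "subspace_align", "ddc")
  if (!all(algorithms %in% valid)) {
    stopf("unknown algorithm(s): %s", paste(setdiff(algorithms, valid), collapse = ", "))
  }
  subjects <- sort(unique(target$subject))
  if (length(subjects) < 2L) stopf("target must contain at least 2 subjects")

  fold_rows <- list(); meas_rows <- list()
  for (fi in seq_along(subjects)) {
    held <- subjects[fi]
    tr <- subset_rows(target, which(target$subject != held))
    te <- subset_rows(target, which(target$subject == held))
    n_tr_rec <- length(unique(paste(tr$subject, tr$recording)))
    src_bal <- balance_source_recordings(source, n_tr_rec)
    fseed <- derive_seed(seed, fi)
    for (alg in algorithms) {
      sc <- fit_and_eval(alg, src_bal, tr, te, head_cfg, fseed)
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = held, algorithm = alg, accuracy = sc$accuracy,
        kappa = sc$kappa, stringsAsFactors = FALSE)
    }
    if (!is.null(measures) && length(measures) > 0L) {
      mr <- compute_measures(src_bal, tr, measures = measures,
                             subspace_k = head_cfg$subspace_k %||% 100L,
                             downsample = head_cfg$downsample %||% 10L,
                             seed = fseed)
      mr <- cbind(fold = held, mr, stringsAsFactors = FALSE)
      meas_rows[[length(meas_rows) + 1L]] <- mr
    }
  }
  folds <- do.call(rbind, fold_rows)
  meas <- if (length(meas_rows)) do.call(rbind, meas_rows) else NULL

  summary_df <- do.call(rbind, lapply(sort(unique(folds$algorithm)), function(a) {
    sub <- folds[folds$algorithm == a, ]
    data.frame(algorithm = a,
               mean_accuracy = mean(sub$accuracy), sd_accuracy = sd(sub$accuracy),
               mean_kappa = mean(sub$kappa), sd_kappa = sd(sub$kappa),
               n_folds = nrow(sub), stringsAsFactors = FALSE)
  }))
  tallies <- tally_best(folds)
  tallies_df <- data.frame(algorithm = names(tallies), fraction_best = unname(tallies),
                           stringsAsFactors = FALSE)

  ttests_df <- NULL
  if ("head_retrain" %in% algorithms && length(algorithms) > 1L) {
    base <- folds[folds$algorithm == "head_retrain", ]
    base <- base[order(base$fold), ]
    ttests_df <- do.call(rbind, lapply(setdiff(algorithms, "head_retrain"), function(a) {
      sub <- folds[folds$algorithm == a, ]
      sub <- sub[order(sub$fold), ]
      res <- tryCatch(paired_ttest(sub$accuracy, base$accuracy),
                      error = function(e) list(t = NA_real_, p = NA_real_,
                                               df = NA_real_, mean_diff = NA_real_))
      data.frame(algorithm = a, t = res$t, p = res$p, df = res$df,
                 mean_diff = res$mean_diff, stringsAsFactors = FALSE)
    }))
  }

  res <- structure(
    list(folds = folds, measures = meas, summary = summary_df,
         tallies = tallies_df, ttests = ttests_df, correlations = NULL,
         algorithms = algorithms, seed = as.integer(seed)),
    class = "benchmark_result"
  )
  if (!is.null(meas)) res$correlations <- correlate_measures(res)
  res
}

#' Correlate transferability measures with fold accuracy
#'
#' For each measure/parameterization and each algorithm, the Spearman rank
#' correlation between the per-fold measure value and the per-fold accuracy,
#' plus a pooled "overall" correlation concatenating all algorithms.
#' Degenerate cells (constant measure or accuracy ranks) are reported with
#' `NA` rather than dropped.  Bonferroni-adjusted significance flags use a
#' family size of (#measures x #columns) by default.
#'
#' @param result a `benchmark_result` with a `measures` table, or a list of
#'   such results (their folds are pooled; folds are disambiguated per run).
#' @param alpha unadjusted significance level for the Bonferroni flag.
#' @param family_size Bonferroni family size; default is the number of
#'   correlation cells computed.
#' @return data.frame with columns `measure`, `params`, `algorithm`,
#'   `rho`, `p`, `n`, `significant_bonferroni`.
#' @export
correlate_measures <- function(result, alpha = 0.05, family_size = NULL) {
  results <- if (inherits(result, "benchmark_result")) list(result) else result
  stopifnot(all(vapply(results, inherits, logical(1L), "benchmark_result")))
  folds <- do.call(rbind, lapply(seq_along(results), function(i) {
    f <- results[[i]]$folds; f$fold <- paste0("run", i, ":", f$fold); f
  }))
  meas <- do.call(rbind, lapply(seq_along(results), function(i) {
    m <- results[[i]]$measures
    if (is.null(m)) stopf("benchmark_result has no measures table")
    m$fold <- paste0("run", i, ":", m$fold); m
  }))
  if (length(unique(folds$fold)) < 3L) stopf("need >= 3 folds to correlate")
  meas$id <- paste(meas$measure, meas$params)
  algos <- sort(unique(folds$algorithm))
  cells <- list()
  for (id in unique(meas$id)) {
    msub <- meas[meas$id == id, , drop = FALSE]
    for (a in c(algos, "overall")) {
      fsub <- if (a == "overall") folds else folds[folds$algorithm == a, ]
      merged <- merge(fsub, msub[, c("fold", "value")], by = "fold")
      res <- tryCatch(spearman_cor(merged$value, merged$accuracy),
                      error = function(e) list(rho = NA_real_, p = NA_real_,
                                               n = nrow(merged)))
      cells[[length(cells) + 1L]] <- data.frame(
        measure = msub$measure[1L], params = msub$params[1L],
        algorithm = a, rho = res$rho, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  fam <- family_size %||% nrow(out)
  out$significant_bonferroni <- !is.na(out$p) & out$p < alpha / fam
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d folds x %d algorithms (seed %d)\n",
              length(unique(x$folds$fold)), length(x$algorithms), x$seed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a benchmark result to JSON (and back)
#'
#' Values are written at full precision so a write/read round trip is
#' lossless.
#'
#' @param result a `benchmark_result`.
#' @param path JSON path.
#' @export
write_benchmark_result <- function(result, path) {
  stopifnot(inherits(result, "benchmark_result"))
  payload <- unclass(result)
  jsonlite::write_json(payload, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_benchmark_result
#' @export
read_benchmark_result <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x) if (is.null(x) || length(x) == 0L) NULL else as.data.frame(x)
  structure(
    list(folds = as_df(raw$folds), measures = as_df(raw$measures),
         summary = as_df(raw$summary), tallies = as_df(raw$tallies),
         ttests = as_df(raw$ttests), correlations = as_df(raw$correlations),
         algorithms = unlist(raw$algorithms), seed = as.integer(raw$seed)),
    class = "benchmark_result"
  )
}
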