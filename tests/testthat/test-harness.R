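test_that("Cohen's kappa matches hand and Monte-Carlo derivations", {
  expect_equal(cohens_kappa(c(1, 2, 1), c(1, 2, 1)), 1)

  # hand-evaluated instance: p_o = 2/3, p_e = 1/2 -> kappa = 1/3
  yt <- c(1, 1, 1, 0, 0, 0)
  yp <- c(1, 1, 0, 0, 0, 1)
  expect_equal(cohens_kappa(yt, yp), 1 / 3)

  # brute-force confusion-matrix oracle on random instances
  withr::with_seed(60, {
    for (i in 1:5) {
      a <- sample(letters[1:4], 30, TRUE)
      b <- sample(letters[1:4], 30, TRUE)
      expect_equal(cohens_kappa(a, b), oracle_kappa(a, b), tolerance = 1e-12)
    }
  })

  # independent predictions sit near zero
  withr::with_seed(61, {
    a <- sample(letters[1:3], 5000, TRUE)
    b <- sample(a)
  })
  expect_lt(abs(cohens_kappa(a, b)), 0.03)

  expect_error(cohens_kappa(1:3, 1:4), "length mismatch")
  # degenerate marginals: identical constant raters agree perfectly,
  # disjoint constant raters have zero chance-corrected agreement
  expect_equal(cohens_kappa(c(1, 1), c(1, 1)), 1)
  expect_equal(cohens_kappa(c("a", "a", "a"), c("b", "b", "b")), 0)
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x - 5)$rho, -1)

  # tied instance against the rank-then-Pearson oracle
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6, 7, 9)
  ours <- spearman_cor(xt, yt)
  orac <- oracle_spearman(xt, yt)
  expect_equal(ours$rho, orac$rho, tolerance = 1e-12)
  expect_equal(ours$p, orac$p, tolerance = 1e-12)

  # and against the stock implementation's asymptotic path
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman",
                                          exact = FALSE))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)

  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
})

test_that("the paired t-test wrapper reports effects and refuses degenerate input", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_error(paired_ttest(a, a + 1), "zero variance")

  withr::with_seed(62, {
    x <- rnorm(30)
    y <- x + rnorm(30, mean = 1, sd = 0.1)
  })
  res <- paired_ttest(y, x)
  expect_lt(res$p, 0.001)
  expect_gt(res$t, 0)

  # antisymmetry under swapping
  expect_equal(paired_ttest(x, y)$t, -res$t)
  expect_equal(res$df, 29)
})

test_that("best-algorithm tallies split ties and check completeness", {
  folds <- expand.grid(fold = paste0("s", 1:4),
                       algorithm = c("a", "b", "c"),
                       stringsAsFactors = FALSE)
  folds$accuracy <- ifelse(folds$algorithm == "a", 0.9, 0.5)
  t1 <- tally_best(folds)
  expect_equal(unname(t1["a"]), 1)
  expect_equal(unname(t1["b"]), 0)

  # exact two-way ties split 0.5/0.5
  folds$accuracy <- ifelse(folds$algorithm == "c", 0.1, 0.8)
  t2 <- tally_best(folds)
  expect_equal(unname(t2[c("a", "b")]), c(0.5, 0.5))
  expect_equal(sum(t2), 1, tolerance = 1e-12)

  # constructed 4-fold instance against a hand tally:
  # s1 -> a, s2 -> b, s3 -> c, s4 -> a/b tie
  folds$accuracy <- c(0.9, 0.2, 0.2, 0.5,   # algorithm a across folds s1..s4
                      0.1, 0.8, 0.2, 0.5,   # algorithm b
                      0.2, 0.3, 0.9, 0.1)   # algorithm c
  t3 <- tally_best(folds)
  expect_equal(unname(t3[c("a", "b", "c")]), c(0.375, 0.375, 0.25))

  expect_error(tally_best(folds[-1, ]), "every algorithm")
})

test_that("source balancing keeps first recordings and an every-nth subset", {
  # 8 source subjects, 2-3 recordings each
  withr::with_seed(63, {
    rows <- list(); labs <- list(); subj <- list(); rec <- list()
    for (s in 1:8) {
      for (r in seq_len(2 + s %% 2)) {
        rows[[length(rows) + 1]] <- matrix(rnorm(20), 10, 2)
        subj[[length(subj) + 1]] <- rep(sprintf("s%02d", s), 10)
        rec[[length(rec) + 1]] <- rep(sprintf("r%02d", r), 10)
        labs[[length(labs) + 1]] <- sample(c("a", "b"), 10, TRUE)
      }
    }
    src <- feature_table(do.call(rbind, rows), unlist(labs), "source",
                         unlist(subj), unlist(rec))
  })
  bal <- sleeptransfer:::balance_source_recordings(src, 4)
  # only first recordings survive
  expect_true(all(bal$recording == "r01"))
  # every 2nd of the 8 first-recordings -> 4 recordings
  expect_equal(length(unique(bal$subject)), 4L)
  expect_equal(unique(bal$subject), c("s01", "s03", "s05", "s07"))
})

test_that("the LOSO benchmark is deterministic, complete, and separable-limit exact", {
  # a separable 3-subject toy: all algorithms reach accuracy 1 on every fold
  blobs <- withr::with_seed(64, {
    X <- rbind(matrix(rnorm(150, 0, 0.1), ncol = 2),
               matrix(rnorm(150, 10, 0.1), ncol = 2))
    y <- rep(c("a", "b"), each = 75)
    sub <- rep(rep(c("s1", "s2", "s3"), each = 25), 2)
    list(src = feature_table(X, y, "source", sub, "r1"),
         tgt = feature_table(X + 0.01, y, "target", sub, "r1"))
  })
  res <- loso_benchmark(blobs$src, blobs$tgt,
                        algorithms = c("head_retrain", "coral", "subspace_align"),
                        measures = NULL, head_cfg = list(subspace_k = 2), seed = 2)
  expect_true(all(res$folds$accuracy == 1))
  expect_true(all(res$folds$kappa == 1))
  # every (fold, algorithm) pair appears exactly once
  expect_equal(nrow(res$folds), 3L * 3L)
  expect_equal(anyDuplicated(res$folds[c("fold", "algorithm")]), 0L)
  expect_equal(sum(res$tallies$fraction_best), 1, tolerance = 1e-12)

  # determinism of the full result given the seed
  pair <- small_domain_pair(shift = 1, n_subjects = 3, epochs = 40, seed = 21)
  b1 <- loso_benchmark(pair$source, pair$target, c("head_retrain", "coral"),
                       measures = c("mmd"), head_cfg = list(subspace_k = 5), seed = 7)
  b2 <- loso_benchmark(pair$source, pair$target, c("head_retrain", "coral"),
                       measures = c("mmd"), head_cfg = list(subspace_k = 5), seed = 7)
  expect_identical(b1$folds, b2$folds)
  expect_identical(b1$measures, b2$measures)

  expect_error(loso_benchmark(pair$source, pair$target, "mystery"), "unknown")
})

test_that("head_retrain folds match a manual train/evaluate composition", {
  pair <- small_domain_pair(shift = 0.5, n_subjects = 3, epochs = 40, seed = 22)
  res <- loso_benchmark(pair$source, pair$target, "head_retrain",
                        measures = NULL, seed = 5)
  for (i in seq_len(nrow(res$folds))) {
    held <- res$folds$fold[i]
    tr_idx <- which(pair$target$subject != held)
    te_idx <- which(pair$target$subject == held)
    fseed <- sleeptransfer:::derive_seed(5, match(held, sort(unique(pair$target$subject))))
    hd <- train_head(pair$target$features[tr_idx, ], pair$target$labels[tr_idx],
                     seed = fseed)
    acc <- mean(predict(hd, pair$target$features[te_idx, ], type = "class")
                == pair$target$labels[te_idx])
    expect_equal(res$folds$accuracy[i], acc)
  }
})

test_that("measure-accuracy correlation tables behave at the identity and degenerate limits", {
  # synthetic benchmark_result whose measure equals fold accuracy -> rho = 1
  folds <- expand.grid(fold = paste0("s", 1:6), algorithm = c("a", "b"),
                       stringsAsFactors = FALSE)
  withr::with_seed(65, acc_per_fold <- runif(6, 0.5, 1))
  folds$accuracy <- acc_per_fold[match(folds$fold, paste0("s", 1:6))]
  folds$kappa <- folds$accuracy
  acc_by_fold <- tapply(folds$accuracy, folds$fold, mean)
  meas <- data.frame(fold = names(acc_by_fold), measure = "echo", params = "",
                     value = as.numeric(acc_by_fold),
                     n_source = 10, n_target = 10, stringsAsFactors = FALSE)
  res <- structure(list(folds = folds, measures = meas, algorithms = c("a", "b"),
                        seed = 1L), class = "benchmark_result")
  tab <- correlate_measures(res)
  # within each algorithm the measure is a monotone image of accuracy
  expect_true(all(tab$rho[tab$algorithm != "overall"] == 1))
  # pooled overall equals spearman on concatenated vectors
  merged <- merge(folds, meas[c("fold", "value")], by = "fold")
  expect_equal(tab$rho[tab$algorithm == "overall"],
               spearman_cor(merged$value, merged$accuracy)$rho)

  # constant measures yield NA cells rather than an error
  meas$value <- 0.5
  res$measures <- meas
  tab2 <- correlate_measures(res)
  expect_true(all(is.na(tab2$rho)))
  expect_true(all(!tab2$significant_bonferroni))
})

test_that("benchmark results survive a JSON round trip losslessly", {
  pair <- small_domain_pair(shift = 1, n_subjects = 3, epochs = 30, seed = 23)
  res <- loso_benchmark(pair$source, pair$target, c("head_retrain", "coral"),
                        measures = c("mmd", "h_score"),
                        head_cfg = list(subspace_k = 5), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_benchmark_result(res, path)
  back <- read_benchmark_result(path)
  expect_equal(back$folds$accuracy, res$folds$accuracy)
  expect_equal(back$folds$kappa, res$folds$kappa)
  expect_equal(back$measures$value, res$measures$value)
  expect_equal(back$summary$mean_accuracy, res$summary$mean_accuracy)
  expect_equal(back$tallies$fraction_best, res$tallies$fraction_best)
  expect_equal(back$correlations$rho, res$correlations$rho)
  expect_identical(back$seed, res$seed)
})
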