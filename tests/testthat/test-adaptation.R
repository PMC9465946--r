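test_that("CORAL reproduces isotropic scaling and matches target covariance", {
  # construct samples with cov 4*I (source) and I (target): A = I/2
  n <- 4
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt((n - 1) / 2)
  Xs <- base * 2   # cov = 4 I
  Xt <- base       # cov = I
  ad <- fit_coral(Xs, Xt, shrinkage = 0)
  expect_equal(ad$A, diag(0.5, 2), tolerance = 1e-10)
  Z <- apply_coral(ad, Xs)
  expect_equal(cov(Z), diag(1, 2), tolerance = 1e-10)

  # Xs = Xt: transformed covariance equals the target covariance
  withr::with_seed(21, X <- matrix(rnorm(400), 100, 4))
  ad2 <- fit_coral(X, X, shrinkage = 0)
  expect_equal(cov(apply_coral(ad2, X)), cov(X), tolerance = 1e-10)

  # random full-rank 5-D tables: Eq-style objective at the optimum
  withr::with_seed(22, {
    Xs5 <- matrix(rnorm(2500), 500, 5) %*% matrix(rnorm(25), 5, 5)
    Xt5 <- matrix(rnorm(2500), 500, 5) %*% matrix(rnorm(25), 5, 5)
  })
  ad5 <- fit_coral(Xs5, Xt5, shrinkage = 0)
  resid <- norm(t(ad5$A) %*% ad5$cov_s$cov %*% ad5$A - ad5$cov_t$cov, "F")
  expect_lt(resid, 1e-8)

  expect_error(fit_coral(Xs5, Xt5[, 1:3]), "dimension mismatch")
  expect_error(apply_coral(ad5, Xs5[, 1:3]), "dimension mismatch")
})

test_that("CORAL recentring and metadata pass-through behave as documented", {
  withr::with_seed(23, {
    Xs <- matrix(rnorm(200, 5), 50, 4)
    Xt <- matrix(rnorm(200, -3), 50, 4)
  })
  fts <- make_ft(Xs, labels = rep(c("N2", "REM"), 25))
  ad_none <- fit_coral(fts, Xt, recenter = "none")
  ad_tgt <- fit_coral(fts, Xt, recenter = "target")
  Z_none <- apply_coral(ad_none, fts)
  Z_tgt <- apply_coral(ad_tgt, fts)
  expect_equal(unname(colMeans(Z_none$features)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(colMeans(Z_tgt$features)), unname(colMeans(Xt)),
               tolerance = 1e-10)
  expect_identical(Z_tgt$labels, fts$labels)

  # A = I on identity-covariance data with recenter none: output = centered input
  nI <- 4
  baseI <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt((nI - 1) / 2) + 7
  adI <- fit_coral(baseI, baseI + 2, shrinkage = 0)
  expect_equal(adI$A, diag(1, 2), tolerance = 1e-10)
  expect_equal(apply_coral(adI, baseI), sweep(baseI, 2, colMeans(baseI)),
               tolerance = 1e-10)
})

test_that("perturbing the CORAL optimum never improves the objective", {
  withr::with_seed(24, {
    Xs <- matrix(rnorm(1000), 200, 5)
    Xt <- matrix(rnorm(1000), 200, 5) %*% diag(c(2, 1.5, 1, 0.7, 0.5))
  })
  ad <- fit_coral(Xs, Xt)
  Cs <- ad$cov_s$cov; Ct <- ad$cov_t$cov
  obj <- function(A) norm(t(A) %*% Cs %*% A - Ct, "F")^2
  base <- obj(ad$A)
  withr::with_seed(25, {
    for (i in 1:20) {
      D <- matrix(rnorm(25), 5, 5)
      D <- D / norm(D, "F") * 1e-3
      expect_gte(obj(ad$A + D), base)
    }
  })
})

test_that("Per-Class CORAL aligns class covariances and falls back per the rule", {
  withr::with_seed(26, {
    XsA <- matrix(rnorm(300, sd = 1), 100, 3)
    XsB <- matrix(rnorm(300, sd = 3), 100, 3)
    XtA <- matrix(rnorm(300, sd = 2), 100, 3) + 1
    XtB <- matrix(rnorm(300, sd = 0.5), 100, 3) - 1
  })
  fts <- make_ft(rbind(XsA, XsB), labels = rep(c("A", "B"), each = 100))
  ftt <- make_ft(rbind(XtA, XtB), labels = rep(c("A", "B"), each = 100),
                 domain = "target")
  ad <- fit_per_class_coral(fts, ftt, shrinkage = 0)
  expect_length(ad$fallback_classes, 0)
  Z <- apply_per_class_coral(ad, fts)
  for (cl in c("A", "B")) {
    zc <- Z$features[Z$labels == cl, ]
    tc <- ftt$features[ftt$labels == cl, ]
    expect_equal(cov(zc), cov(tc), tolerance = 1e-8)
  }

  # single-class data reduces to global CORAL bit for bit
  fts1 <- make_ft(XsA, labels = rep("A", 100))
  ftt1 <- make_ft(XtA, labels = rep("A", 100), domain = "target")
  pc <- fit_per_class_coral(fts1, ftt1)
  gl <- fit_coral(fts1, ftt1)
  expect_identical(pc$per_class[["A"]]$A, gl$A)
  expect_identical(apply_per_class_coral(pc, fts1)$features,
                   apply_coral(gl, fts1)$features)

  # class present in source only uses the global transform and is flagged
  fts2 <- make_ft(rbind(XsA, XsB), labels = rep(c("A", "C"), each = 100))
  ad2 <- fit_per_class_coral(fts2, ftt, min_class_n = 5)
  expect_true("C" %in% ad2$fallback_classes)
  expect_error(fit_per_class_coral(fts2, ftt, min_class_n = 1000,
                                   global_fallback = FALSE), "fallback")
})

test_that("Per-Class CORAL with one shared label reproduces CORAL on any data", {
  withr::with_seed(27, {
    Xs <- matrix(rnorm(240), 60, 4)
    Xt <- matrix(rnorm(240, 1), 60, 4)
  })
  fts <- make_ft(Xs, labels = rep("N2", 60))
  ftt <- make_ft(Xt, labels = rep("N2", 60), domain = "target")
  expect_identical(
    apply_per_class_coral(fit_per_class_coral(fts, ftt, recenter = "target"), fts)$features,
    apply_coral(fit_coral(fts, ftt, recenter = "target"), fts)$features)
})

test_that("subspace alignment has contractive aligner and recovers rotations", {
  # Xs = Xt: aligned source equals projected target exactly
  withr::with_seed(28, X <- matrix(rnorm(90), 30, 3))
  sa <- fit_subspace_alignment(X, X, 3)
  expect_equal(apply_subspace_alignment(sa, X, "source"),
               apply_subspace_alignment(sa, X, "target"), tolerance = 1e-12)

  # singular values of M never exceed 1
  withr::with_seed(29, { A <- matrix(rnorm(500), 100, 5); B <- matrix(rnorm(500), 100, 5) })
  sa2 <- fit_subspace_alignment(A, B, 4)
  expect_lte(max(svd(sa2$M)$d), 1 + 1e-8)

  # a rotated copy: the aligned source basis coincides with the target
  # basis (V_s M = V_t at full rank), and the aligned-source coordinate
  # covariance has the same spectrum as the target coordinates
  theta <- pi / 6
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  withr::with_seed(30, S <- matrix(rnorm(200), 100, 2) %*% diag(c(3, 1)))
  T_ <- S %*% t(R)
  sa3 <- fit_subspace_alignment(S, T_, 2)
  expect_equal(sa3$V_s$basis %*% sa3$M, sa3$V_t$basis,
               tolerance = 1e-10, ignore_attr = TRUE)
  ev_a <- eigen(cov(apply_subspace_alignment(sa3, S, "source")))$values
  ev_t <- eigen(cov(apply_subspace_alignment(sa3, T_, "target")))$values
  expect_equal(ev_a, ev_t, tolerance = 1e-8)

  # permutation invariance of the fit
  perm <- withr::with_seed(31, sample.int(100))
  sa4 <- fit_subspace_alignment(A[perm, ], B, 4)
  expect_equal(sa4$M, sa2$M, tolerance = 1e-10)

  # k is truncated to the data rank with a warning
  low <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(8), 2, 4)
  expect_warning(sal <- fit_subspace_alignment(low, low, 4), "truncated")
  expect_equal(sal$k, 2L)
  expect_error(fit_subspace_alignment(A[1, , drop = FALSE], B), "insufficient")
})

test_that("the head classifier separates blobs, matches chance, and is deterministic", {
  blobs <- separable_blobs()
  hd <- train_head(blobs$X, blobs$y, seed = 4)
  expect_equal(mean(predict(hd, blobs$X, type = "class") == blobs$y), 1.0)
  P <- predict(hd, blobs$X, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  expect_true(all(P >= 0))

  # permuted labels, 5 balanced classes: held-out accuracy at chance
  withr::with_seed(33, {
    X <- matrix(rnorm(2000 * 4), 2000, 4)
    y <- sample(rep(letters[1:5], 400))
  })
  tr <- 1:1000; te <- 1001:2000
  hd2 <- train_head(X[tr, ], y[tr], seed = 5)
  acc <- mean(predict(hd2, X[te, ], type = "class") == y[te])
  expect_gt(acc, 0.2 - 0.03)
  expect_lt(acc, 0.2 + 0.03)

  # identical seeds give identical weights
  h1 <- train_head(blobs$X, blobs$y, seed = 11)
  h2 <- train_head(blobs$X, blobs$y, seed = 11)
  expect_identical(stats::coef(h1$fit), stats::coef(h2$fit))

  expect_error(train_head(blobs$X, rep("a", nrow(blobs$X))), "degenerate")
})

test_that("head retraining survives rank-deficient CORAL-transformed inputs", {
  withr::with_seed(34, {
    Xs <- matrix(rnorm(120), 60, 2) %*% matrix(rnorm(10), 2, 5)  # rank 2 in 5-D
    Xt <- matrix(rnorm(120), 60, 2) %*% matrix(rnorm(10), 2, 5)
  })
  fts <- make_ft(Xs, labels = rep(c("a", "b"), 30))
  ftt <- make_ft(Xt, labels = rep(c("a", "b"), 30), domain = "target")
  ad <- fit_coral(fts, ftt, recenter = "target")   # default shrinkage path
  pooled_X <- rbind(apply_coral(ad, fts)$features, ftt$features)
  pooled_y <- c(fts$labels, ftt$labels)
  expect_no_error(train_head(pooled_X, pooled_y, seed = 2))
})

test_that("adaptations serialize to JSON and back at full precision", {
  withr::with_seed(35, {
    Xs <- matrix(rnorm(200), 50, 4)
    Xt <- matrix(rnorm(200, 1), 50, 4)
  })
  fts <- make_ft(Xs, labels = rep(c("a", "b"), 25))
  ftt <- make_ft(Xt, labels = rep(c("a", "b"), 25), domain = "target")
  path <- withr::local_tempfile(fileext = ".json")

  for (ad in list(fit_coral(fts, ftt),
                  fit_per_class_coral(fts, ftt, min_class_n = 5),
                  suppressWarnings(fit_subspace_alignment(fts, ftt, 3)))) {
    write_adaptation(ad, path)
    back <- read_adaptation(path)
    expect_equal(back$kind, ad$kind)
    if (ad$kind == "coral") {
      expect_equal(back$A, ad$A, ignore_attr = TRUE)
      expect_equal(apply_coral(back, fts)$features, apply_coral(ad, fts)$features,
                   ignore_attr = TRUE)
    }
    if (ad$kind == "subspace_align") expect_equal(back$M, ad$M, ignore_attr = TRUE)
    if (ad$kind == "per_class_coral") {
      expect_equal(apply_per_class_coral(back, fts)$features,
                   apply_per_class_coral(ad, fts)$features)
    }
  }
})

test_that("the DDC trainer reduces hidden-layer MMD and respects its contracts", {
  pair <- small_domain_pair(shift = 2, n_subjects = 3, epochs = 40, seed = 6)
  # identical source and target: full-set hidden MMD vanishes, and the
  # per-batch unbiased estimates average out near zero
  md0 <- ddc_reference_train(pair$source, NULL, pair$source, NULL,
                             lambda = 1, epochs = 5, seed = 3)
  expect_lt(md0$final_mmd2, 1e-6)
  expect_lt(abs(mean(md0$trace$mmd2)), 0.05)

  # determinism given seed
  m1 <- ddc_reference_train(pair$source, NULL, pair$target, NULL,
                            lambda = 1, epochs = 3, seed = 9)
  m2 <- ddc_reference_train(pair$source, NULL, pair$target, NULL,
                            lambda = 1, epochs = 3, seed = 9)
  expect_identical(m1$weights, m2$weights)

  # lambda = 0 is plain supervised training: mmd2 trace identically zero
  m3 <- ddc_reference_train(pair$source, NULL, pair$target, NULL,
                            lambda = 0, epochs = 3, seed = 9)
  expect_equal(m3$trace$mmd2, rep(0, 3))

  # predictions are valid classes and the task loss decreases
  preds <- predict(m1, pair$target, type = "class")
  expect_true(all(preds %in% m1$classes))
  expect_lt(tail(m3$trace$task_loss, 1), m3$trace$task_loss[1])

  expect_error(ddc_reference_train(pair$source, NULL,
                                   matrix(numeric(0), 0, 10), NULL), "nonempty")
  expect_error(ddc_reference_train(pair$source, NULL, pair$target, NULL,
                                   lambda = -1), "lambda")
})
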