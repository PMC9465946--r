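#' Posterior matrices for LEEP
#'
#' Container for the softmax outputs of a source-trained model evaluated on
#' target samples, paired with the true target labels.  Rows must be valid
#' probability vectors over the source label space.
#'
#' @param theta n x Z numeric matrix; each row sums to 1 (tolerance 1e-8)
#'   with entries in `[0, 1]`.
#' @param labels length-n true target class labels.
#' @return object of class `posterior_matrix`.
#' @export
posterior_matrix <- function(theta, labels) {
  if (is.data.frame(theta)) theta <- as.matrix(theta)
  if (!is.matrix(theta) || !is.numeric(theta)) stopf("`theta` must be a numeric matrix")
  if (nrow(theta) < 1L || ncol(theta) < 2L) stopf("`theta` needs n >= 1 rows and Z >= 2 columns")
  if (length(labels) != nrow(theta)) stopf("`labels` must have one entry per row of `theta`")
  if (any(theta < -1e-12) || any(theta > 1 + 1e-12)) stopf("posterior entries must lie in [0, 1]")
  rs <- rowSums(theta)
  bad <- which(abs(rs - 1) > 1e-8)
  if (length(bad) > 0L) stopf("posterior row %d sums to %.10f, not 1", bad[1L], rs[bad[1L]])
  structure(list(theta = theta, labels = as.character(labels)),
            class = "posterior_matrix")
}

#' Read a posterior matrix from CSV
#'
#' Expected header: `p_0,...,p_{Z-1},label`.
#'
#' @param path CSV path.
#' @return a [posterior_matrix()].
#' @export
load_posterior_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stopf("missing required column \"label\" in %s", path)
  posterior_matrix(as.matrix(df[setdiff(names(df), "label")]), df$label)
}

#' Log expected empirical prediction (LEEP)
#'
#' Builds the empirical Bayes classifier over the source-label outputs: the
#' joint `P(y, z)` is the average posterior mass that samples of true class
#' `y` put on source label `z`, and `P(y | z) = P(y, z) / P(z)`.  LEEP is
#' the mean over samples of `log sum_z P(y_i | z) theta_iz` — the average
#' log-likelihood of that classifier on the target set.  Always <= 0; 0 is
#' attained only by a perfect one-hot predictor.
#'
#' @param post a [posterior_matrix()].
#' @return scalar LEEP value (non-positive).
#' @export
leep <- function(post) {
  if (!inherits(post, "posterior_matrix")) {
    stopf("`post` must be a posterior_matrix")
  }
  theta <- post$theta
  y <- factor(post$labels)
  n <- nrow(theta)
  ## joint P(y, z): |Y| x Z
  joint <- rowsum(theta, y) / n
  pz <- colMeans(theta)
  cond <- sweep(joint, 2L, pmax(pz, 1e-300), "/")   # P(y | z)
  lik <- rowSums(theta * cond[as.integer(y), , drop = FALSE])
  mean(log(pmax(lik, 1e-300)))
}

#' H-score of a feature representation
#'
#' `H = tr(cov(phi)^{-1} cov(E[phi | Y]))`: the between-class covariance of
#' the class-conditional feature means (weighted by class frequencies)
#' measured in the metric of the total feature covariance.  Population
#' (1/n) covariance normalization is used on both factors, consistent with
#' the law of total covariance.  Large values indicate class-discriminative
#' features; 0 means the class means coincide.
#'
#' @param phi n x d feature matrix or [feature_table()].
#' @param y length-n class labels (from the feature table when `NULL`).
#' @param pseudoinverse use the Moore-Penrose pseudoinverse of the total
#'   covariance (default `TRUE`); with `FALSE` a singular covariance errors.
#' @return scalar H-score (>= 0 up to rounding).
#' @export
h_score <- function(phi, y = NULL, pseudoinverse = TRUE) {
  if (is_feature_table(phi) && is.null(y)) y <- phi$labels
  X <- as_matrix_input(phi)
  if (nrow(X) < 2L) stopf("H-score needs n >= 2 samples")
  if (is.null(y) || length(y) != nrow(X)) stopf("`y` must supply one label per row")
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stopf("degenerate labels: need >= 2 classes")
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  cov_total <- crossprod(Xc) / n
  p <- as.numeric(table(y)) / n
  class_means <- rowsum(X, y) / as.numeric(table(y))
  Mc <- sweep(class_means, 2L, mu)
  cov_between <- crossprod(Mc * sqrt(p), Mc * sqrt(p))
  inv <- if (pseudoinverse) {
    s <- sym_psd_power(cov_total, -1)
    s$mat
  } else {
    ev <- eigen(cov_total, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= RANK_TOL * max(ev)) {
      stopf("total covariance is singular; set pseudoinverse = TRUE")
    }
    solve(cov_total)
  }
  sum(diag(inv %*% cov_between))
}

## deterministic stride downsampling with a seeded circular offset
stride_downsample <- function(n, factor, seed) {
  if (factor <= 1L) return(seq_len(n))
  off <- with_seed(seed, sample.int(factor, 1L))
  idx <- seq(off, length.out = ceiling(n / factor), by = factor)
  (idx - 1L) %% n + 1L
}

#' Average hypothesis margin between source and target features
#'
#' Dataset membership (source vs target) plays the role of the class: for
#' each point in the downsampled union, the margin is half the difference
#' between the distance to its nearest point in the *other* dataset
#' (nearmiss) and its nearest point in the *same* dataset excluding itself
#' (nearhit).  The value is the mean margin over the union.  Positive
#' values indicate the two feature clouds are mutually separated.
#'
#' @param Xs_feats,Xt_feats source/target feature matrices or
#'   [feature_table()]s.
#' @param downsample stride factor applied independently to each set
#'   (default 10); 1 disables downsampling.
#' @param seed seed for the circular stride offsets.
#' @return scalar mean margin.
#' @export
hypothesis_margin <- function(Xs_feats, Xt_feats, downsample = 10L, seed = 1L) {
  Xs <- as_matrix_input(Xs_feats); Xt <- as_matrix_input(Xt_feats)
  if (ncol(Xs) != ncol(Xt)) stopf("dimension mismatch between source and target features")
  Xs <- Xs[stride_downsample(nrow(Xs), downsample, seed), , drop = FALSE]
  Xt <- Xt[stride_downsample(nrow(Xt), downsample, seed + 1L), , drop = FALSE]
  if (nrow(Xs) < 2L || nrow(Xt) < 2L) {
    stopf("insufficient data: each set needs >= 2 points after downsampling")
  }
  Dss <- sqrt(cross_sqdist(Xs, Xs)); diag(Dss) <- Inf
  Dtt <- sqrt(cross_sqdist(Xt, Xt)); diag(Dtt) <- Inf
  Dst <- sqrt(cross_sqdist(Xs, Xt))
  margins_s <- 0.5 * (apply(Dst, 1L, min) - apply(Dss, 1L, min))
  margins_t <- 0.5 * (apply(Dst, 2L, min) - apply(Dtt, 1L, min))
  mean(c(margins_s, margins_t))
}

#' Cross-dataset silhouette score
#'
#' Silhouette with the two datasets as the two clusters: for each point,
#' `a` is its mean distance to the other points of its own dataset and `b`
#' its mean distance to the other dataset; the silhouette is
#' `(b - a) / max(a, b)` (the classic convention: +1 for well-separated
#' datasets, ~0 for fully overlapping ones), averaged over the union.
#' Points with `a = b = 0` contribute 0.
#'
#' @inheritParams hypothesis_margin
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_cross <- function(Xs_feats, Xt_feats) {
  Xs <- as_matrix_input(Xs_feats); Xt <- as_matrix_input(Xt_feats)
  if (nrow(Xs) < 2L || nrow(Xt) < 2L) stopf("both sets need >= 2 points")
  if (ncol(Xs) != ncol(Xt)) stopf("dimension mismatch between source and target features")
  ns <- nrow(Xs); nt <- nrow(Xt)
  Dss <- sqrt(cross_sqdist(Xs, Xs))
  Dtt <- sqrt(cross_sqdist(Xt, Xt))
  Dst <- sqrt(cross_sqdist(Xs, Xt))
  a_s <- rowSums(Dss) / (ns - 1); b_s <- rowMeans(Dst)
  a_t <- rowSums(Dtt) / (nt - 1); b_t <- colMeans(Dst)
  sil <- function(a, b) ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  mean(c(sil(a_s, b_s), sil(a_t, b_t)))
}

#' Target density around source (TDAS)
#'
#' After subspace alignment, the similarity between a source and a target
#' sample is the dot product of their aligned subspace coordinates,
#' `sim(x_s, x_t) = (x_s V_s M) . (x_t V_t)`.  TDAS is the average, over
#' source samples, of the number of target samples whose similarity is at
#' least `eps_scale * m`, where `m` is the median pairwise Euclidean
#' distance within the target set.  Values range from 0 to `|X_t|`; the
#' dot-product similarity is compared against the distance-derived
#' threshold as defined, without normalization.
#'
#' @param Xs,Xt source/target feature matrices or [feature_table()]s.
#' @param k subspace dimension passed to [fit_subspace_alignment()]
#'   (default 100; truncated to the data rank).
#' @param eps_scale threshold scale, conventionally 0.1, 1 or 10.
#' @param adapt optional pre-fitted subspace alignment to reuse.
#' @return scalar in `[0, |X_t|]`.
#' @export
tdas <- function(Xs, Xt, k = 100L, eps_scale = 1, adapt = NULL) {
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  m <- median(dist(Xt))
  if (!is.finite(m) || m <= 0) stopf("degenerate threshold: median target distance is 0")
  if (is.null(adapt)) {
    adapt <- suppressWarnings(fit_subspace_alignment(Xs, Xt, k))
  }
  Ps <- apply_subspace_alignment(adapt, Xs, "source")
  Pt <- apply_subspace_alignment(adapt, Xt, "target")
  sims <- tcrossprod(Ps, Pt)
  mean(rowSums(sims >= eps_scale * m))
}

#' MMD as a transferability measure
#'
#' The quadratic-estimator squared MMD between source and target features
#' under an RBF kernel whose bandwidth comes from the median heuristic on
#' the pooled data, optionally scaled by `gamma_scale` (0.1, 1 or 10) to
#' probe bandwidth sensitivity.
#'
#' @inheritParams tdas
#' @param gamma_scale bandwidth scale factor.
#' @return scalar squared MMD (>= 0 up to rounding).
#' @export
mmd_measure <- function(Xs, Xt, gamma_scale = 1) {
  Xs <- as_matrix_input(Xs); Xt <- as_matrix_input(Xt)
  kern <- median_heuristic(rbind(Xs, Xt), scale = gamma_scale)
  mmd2_quadratic(Xs, Xt, kern)$mmd2
}

#' Compute a panel of transferability measures
#'
#' Runs the package's six measures (with the conventional parameter grids
#' for TDAS and MMD) on a source/target pair and returns a tidy report.
#' LEEP needs model posteriors on the target; when `posteriors` is `NULL`
#' and `train_leep_head = TRUE`, a head is trained on the source features
#' and evaluated on the target to produce them.
#'
#' @param source,target [feature_table()]s.
#' @param measures character vector among `"leep"`, `"h_score"`,
#'   `"hypothesis_margin"`, `"silhouette"`, `"tdas"`, `"mmd"`.
#' @param posteriors optional [posterior_matrix()] for LEEP.
#' @param train_leep_head train a source head for LEEP posteriors when none
#'   are supplied.
#' @param subspace_k subspace dimension for TDAS.
#' @param downsample stride factor for the hypothesis margin.
#' @param seed integer seed for the stochastic components.
#' @return data.frame with columns `measure`, `params`, `value`,
#'   `n_source`, `n_target`.
#' @export
compute_measures <- function(source, target,
                             measures = c("leep", "h_score", "hypothesis_margin",
                                          "silhouette", "tdas", "mmd"),
                             posteriors = NULL, train_leep_head = TRUE,
                             subspace_k = 100L, downsample = 10L, seed = 1L) {
  stopifnot(is_feature_table(source), is_feature_table(target))
  measures <- match.arg(measures, several.ok = TRUE)
  ns <- nrow(source$features); nt <- nrow(target$features)
  rows <- list()
  add <- function(measure, params, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, params = params, value = value,
      n_source = ns, n_target = nt, stringsAsFactors = FALSE)
  }
  if ("leep" %in% measures) {
    if (is.null(posteriors) && train_leep_head) {
      hd <- train_head(source, seed = seed)
      posteriors <- posterior_matrix(predict(hd, target, type = "prob"),
                                     target$labels)
    }
    if (!is.null(posteriors)) add("leep", "", leep(posteriors))
  }
  if ("h_score" %in% measures) add("h_score", "", h_score(target))
  if ("hypothesis_margin" %in% measures) {
    add("hypothesis_margin", sprintf("downsample=%d", downsample),
        hypothesis_margin(source, target, downsample, seed))
  }
  if ("silhouette" %in% measures) add("silhouette", "", silhouette_cross(source, target))
  if ("tdas" %in% measures) {
    sa <- suppressWarnings(fit_subspace_alignment(source, target, subspace_k))
    for (es in c(0.1, 1, 10)) {
      add("tdas", sprintf("eps_scale=%g", es),
          tdas(source, target, subspace_k, es, adapt = sa))
    }
  }
  if ("mmd" %in% measures) {
    for (gs in c(0.1, 1, 10)) {
      add("mmd", sprintf("gamma_scale=%g", gs), mmd_measure(source, target, gs))
    }
  }
  do.call(rbind, rows)
}

#' Write a measure report as JSON
#'
#' @param report data.frame from [compute_measures()].
#' @param path output path.
#' @export
write_measure_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
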