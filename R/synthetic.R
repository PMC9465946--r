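#' Default sleep-stage class priors
#'
#' An imbalanced five-stage prior (Wake, N1, N2, N3, REM) with the usual
#' N2 dominance seen in overnight recordings.  The exact values are a
#' documented convention of this package, used as the generator default.
#'
#' @return named length-5 numeric simplex.
#' @export
default_sleep_priors <- function() {
  c(Wake = 0.17, N1 = 0.05, N2 = 0.45, N3 = 0.13, REM = 0.20)
}

#' Configuration for the synthetic domain-shift generator
#'
#' Describes a class-conditional Gaussian feature model shared by a source
#' and a target domain, with a parametric source-to-target shift modelling
#' signal attenuation in a lower-SNR sensor: the class means (which sit on
#' a positive activation baseline) are uniformly scaled by a gain `g < 1`
#' chosen so that the mean activation vector is displaced by
#' `shift * within_class_sd`, while the noise floor stays fixed.  A larger
#' `shift` therefore both moves the target cloud and shrinks its
#' class-discriminative structure, as a weaker sensor would.  Target class
#' means can additionally be rotated by `rotation_angle` in a seeded random
#' 2-plane, and target covariances scaled by `cov_scale`.  Each domain has
#' `n_subjects` subjects with a
#' per-subject mean offset drawn from `N(0, subject_sd^2)` and a uniform
#' number of recordings in `recordings_range`; the default cohort shape
#' (24 subjects, 1-6 recordings each) mirrors a wearable-EEG study design.
#'
#' @param n_classes number of classes K (default 5 sleep stages).
#' @param dim feature dimension d.
#' @param class_priors length-K simplex; defaults to
#'   [default_sleep_priors()] when K = 5, else uniform.
#' @param feature_baseline mean activation level added to every class mean;
#'   learned (post-ReLU) features have a positive baseline, and the shift
#'   attenuates it.  Must satisfy
#'   `feature_baseline * sqrt(dim) > shift * within_class_sd` for the gain
#'   to stay positive (it is floored at 0 otherwise).
#' @param class_mean_spread sd of the seeded class-mean positions around
#'   the baseline.
#' @param within_class_sd within-class feature sd (isotropic).
#' @param shift target mean displacement in units of `within_class_sd`.
#' @param rotation_angle radians of rotation applied to target class means
#'   in a seeded random 2-plane.
#' @param cov_scale multiplier on the target within-class variance.
#' @param subject_sd sd of per-subject mean offsets.
#' @param n_subjects subjects per domain.
#' @param recordings_range integer range (length 2) of recordings per subject.
#' @param epochs_per_recording 30-s epochs per recording.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return object of class `shift_config`.
#' @export
shift_config <- function(n_classes = 5L, dim = 10L, class_priors = NULL,
                         feature_baseline = 1.5, class_mean_spread = 0.7,
                         within_class_sd = 1,
                         shift = 0, rotation_angle = 0, cov_scale = 1,
                         subject_sd = 0.3, n_subjects = 24L,
                         recordings_range = c(1L, 6L),
                         epochs_per_recording = 120L, seed = 1L) {
  if (n_classes < 2L) stopf("`n_classes` must be >= 2")
  if (is.null(class_priors)) {
    class_priors <- if (n_classes == 5L) default_sleep_priors()
                    else rep(1 / n_classes, n_classes)
  }
  if (length(class_priors) != n_classes) stopf("`class_priors` must have length %d", n_classes)
  if (any(class_priors < 0) || abs(sum(class_priors) - 1) > 1e-12) {
    stopf("`class_priors` must be nonnegative and sum to 1")
  }
  for (nm in c("class_mean_spread", "within_class_sd", "cov_scale")) {
    if (get(nm) <= 0) stopf("`%s` must be > 0", nm)
  }
  if (subject_sd < 0) stopf("`subject_sd` must be >= 0")
  if (shift < 0) stopf("`shift` must be >= 0")
  if (length(recordings_range) != 2L || recordings_range[1L] < 1L ||
      recordings_range[2L] < recordings_range[1L]) {
    stopf("`recordings_range` must be an increasing pair of positive integers")
  }
  if (n_subjects < 1L || epochs_per_recording < 1L) {
    stopf("infeasible config: need >= 1 subject and >= 1 epoch per recording")
  }
  structure(
    list(n_classes = as.integer(n_classes), dim = as.integer(dim),
         class_priors = class_priors, feature_baseline = feature_baseline,
         class_mean_spread = class_mean_spread,
         within_class_sd = within_class_sd, shift = shift,
         rotation_angle = rotation_angle, cov_scale = cov_scale,
         subject_sd = subject_sd, n_subjects = as.integer(n_subjects),
         recordings_range = as.integer(recordings_range),
         epochs_per_recording = as.integer(epochs_per_recording),
         seed = as.integer(seed)),
    class = "shift_config"
  )
}

#' @export
print.shift_config <- function(x, ...) {
  cat(sprintf(paste0("<shift_config> K = %d, d = %d, shift = %g, rotation = %g,",
                     " cov_scale = %g\n  %d subjects x %d-%d recordings x %d epochs,",
                     " seed = %d\n"),
              x$n_classes, x$dim, x$shift, x$rotation_angle, x$cov_scale,
              x$n_subjects, x$recordings_range[1L], x$recordings_range[2L],
              x$epochs_per_recording, x$seed))
  invisible(x)
}

## rotation by `angle` in the plane spanned by orthonormal u, v (d >= 2)
plane_rotation <- function(u, v, angle) {
  d <- length(u)
  diag(d) +
    sin(angle) * (tcrossprod(v, u) - tcrossprod(u, v)) +
    (cos(angle) - 1) * (tcrossprod(u, u) + tcrossprod(v, v))
}

sample_domain <- function(means, sd, priors, n_subjects, rec_range,
                          epochs, subject_sd, domain, prefix) {
  K <- nrow(means); d <- ncol(means)
  feats <- list(); labs <- list(); subj <- list(); rec <- list()
  cls_names <- rownames(means)
  for (s in seq_len(n_subjects)) {
    offset <- rnorm(d, sd = subject_sd)
    rng <- seq(rec_range[1L], rec_range[2L])
    n_rec <- if (length(rng) == 1L) rng else sample(rng, 1L)
    for (r in seq_len(n_rec)) {
      y <- sample.int(K, epochs, replace = TRUE, prob = priors)
      X <- means[y, , drop = FALSE] +
        matrix(rnorm(epochs * d, sd = sd), epochs, d) +
        matrix(offset, epochs, d, byrow = TRUE)
      feats[[length(feats) + 1L]] <- X
      labs[[length(labs) + 1L]] <- cls_names[y]
      subj[[length(subj) + 1L]] <- rep(sprintf("%s%02d", prefix, s), epochs)
      rec[[length(rec) + 1L]] <- rep(sprintf("r%02d", r), epochs)
    }
  }
  feature_table(do.call(rbind, feats), unlist(labs), domain,
                unlist(subj), unlist(rec))
}

#' Generate a domain-shifted source/target feature pair
#'
#' Draws class-conditional Gaussian features for a source and a target
#' domain under a [shift_config()].  The two domains share seeded class
#' means centered on the positive activation baseline; the target means are
#' attenuated by the gain `g = max(0, 1 - shift * within_class_sd /
#' (feature_baseline * sqrt(dim)))`, which displaces the mean activation
#' vector by `shift * within_class_sd` toward zero and shrinks the
#' between-class structure by the same factor.  Target class means are then
#' rotated in a seeded 2-plane by `rotation_angle`, and the target
#' within-class sd is scaled by `sqrt(cov_scale)`.  Subject and recording
#' IDs are populated per domain.  The output is bit-reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [shift_config()].
#' @return list with elements `source` and `target`, both [feature_table()]s.
#' @export
make_domain_pair <- function(cfg) {
  stopifnot(inherits(cfg, "shift_config"))
  with_seed(cfg$seed, {
    K <- cfg$n_classes; d <- cfg$dim
    means <- matrix(rnorm(K * d, sd = cfg$class_mean_spread), K, d) +
      cfg$feature_baseline
    rownames(means) <- names(cfg$class_priors) %||% paste0("class_", seq_len(K))
    ## sensor-attenuation gain: grand mean displaced by shift * within_sd
    gain <- max(0, 1 - cfg$shift * cfg$within_class_sd /
                     (cfg$feature_baseline * sqrt(d)))
    tgt_means <- gain * means
    if (cfg$rotation_angle != 0 && d >= 2L) {
      u <- rnorm(d); u <- u / sqrt(sum(u^2))
      v <- rnorm(d); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
      tgt_means <- tgt_means %*% t(plane_rotation(u, v, cfg$rotation_angle))
      rownames(tgt_means) <- rownames(means)
    }
    src <- sample_domain(means, cfg$within_class_sd, cfg$class_priors,
                         cfg$n_subjects, cfg$recordings_range,
                         cfg$epochs_per_recording, cfg$subject_sd,
                         "source", "s")
    tgt <- sample_domain(tgt_means, cfg$within_class_sd * sqrt(cfg$cov_scale),
                         cfg$class_priors, cfg$n_subjects,
                         cfg$recordings_range, cfg$epochs_per_recording,
                         cfg$subject_sd, "target", "t")
    list(source = src, target = tgt)
  })
}

#' Generate synthetic model posteriors for LEEP
#'
#' Emulates the softmax outputs of a source-trained model with a chosen
#' argmax accuracy: for each sample a "predicted" source label is drawn
#' equal to the true label with probability `accuracy` (uniform over the
#' other labels otherwise), and the posterior row is a Dirichlet draw
#' concentrated on it.  `concentration = Inf` produces exact one-hot rows.
#'
#' @param y length-n true target labels, coded in `1..Z` or as the first
#'   `K` of `Z` source-label names.
#' @param accuracy probability the peak label equals the true label; must
#'   lie in `[1/K, 1]` where K is the number of distinct true labels.
#' @param Z number of source labels (columns), `Z >= K`.
#' @param concentration Dirichlet concentration added on the peak label;
#'   larger is peakier.  `Inf` gives one-hot rows.
#' @param seed integer seed.
#' @return a [posterior_matrix()].
#' @export
make_posteriors <- function(y, accuracy, Z = NULL, concentration = 20, seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  K <- length(classes)
  Z <- as.integer(Z %||% K)
  if (Z < K) stopf("`Z` must be >= the number of distinct true labels (%d)", K)
  if (accuracy < 1 / K - 1e-12 || accuracy > 1 + 1e-12) {
    stopf("`accuracy` must lie in [1/K, 1] = [%.3f, 1]", 1 / K)
  }
  n <- length(y)
  yi <- match(y, classes)
  with_seed(seed, {
    correct <- runif(n) < accuracy
    peak <- integer(n)
    peak[correct] <- yi[correct]
    nw <- sum(!correct)
    if (nw > 0L) {
      ## uniform over the Z-1 other source labels
      peak[!correct] <- vapply(yi[!correct], function(k) {
        sample(setdiff(seq_len(Z), k), 1L)
      }, integer(1L))
    }
    theta <- if (is.infinite(concentration)) {
      diag(Z)[peak, , drop = FALSE]
    } else {
      G <- matrix(rgamma(n * Z, shape = 1), n, Z)
      G[cbind(seq_len(n), peak)] <- rgamma(n, shape = 1 + concentration)
      G / rowSums(G)
    }
    posterior_matrix(theta, y)
  })
}
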