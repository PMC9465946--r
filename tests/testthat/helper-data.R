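# Small in-code fixtures shared across test files.

make_ft <- function(X, labels = rep("a", nrow(X)), domain = "source",
                    subject = "s1", recording = "r1") {
  feature_table(X, labels, domain, subject, recording)
}

# two labeled Gaussian blobs in 2-D, linearly separable
separable_blobs <- function(n_per = 30, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
               matrix(rnorm(n_per * 2, mean = gap), ncol = 2))
    list(X = X, y = rep(c("a", "b"), each = n_per))
  })
}

small_domain_pair <- function(shift = 0, n_subjects = 4, epochs = 50,
                              recordings = c(1L, 2L), seed = 1) {
  make_domain_pair(shift_config(n_subjects = n_subjects,
                                epochs_per_recording = epochs,
                                recordings_range = recordings,
                                shift = shift, seed = seed))
}
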