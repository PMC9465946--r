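Package: sleeptransfer
Title: Supervised Domain Adaptation and Transferability Measures for
    Sleep-Staging Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for supervised transfer learning between a source and a
    target domain of learned sleep-staging features, such as features
    extracted from clinical polysomnograms and from wearable single-channel
    EEG.  Implements correlation alignment (CORAL) and a per-class variant,
    subspace alignment, head re-training, and a reference trainer with a
    maximum mean discrepancy (MMD) penalty on hidden activations (deep
    domain confusion).  Provides six transferability measures (LEEP,
    H-score, hypothesis margin, cross-dataset silhouette, target density
    around source, and MMD with median-heuristic bandwidths), a synthetic
    generator of multi-subject, class-imbalanced, domain-shifted feature
    data, and a leave-one-subject-out benchmarking harness reporting
    accuracy, Cohen's kappa, best-algorithm tallies, paired t-tests, and
    Spearman correlations of each measure with fold accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    cluster,
    yaml
Config/testthat/edition: 3
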