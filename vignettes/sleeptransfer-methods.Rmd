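---
title: "Methods: domain adaptation and transferability estimation for sleep-staging features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain adaptation and transferability estimation for sleep-staging features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automatic sleep staging assigns each 30-second epoch of EEG to one of five
stages (Wake, N1, N2, N3, REM).  Models trained on large clinical
polysomnogram corpora degrade when applied to wearable sensors — a single
forehead channel with different placement, lower signal-to-noise ratio, and
a different population.  `sleeptransfer` operates at the *learned-feature*
level: each epoch is represented by the activations of a frozen feature
extractor (a real vector), tagged with its class label, its domain
(`source` = clinical-style, `target` = wearable-style), a subject ID, and a
within-subject recording ID.

The package answers two questions:

1. **Which supervised adaptation recipe helps?**  Head re-training, CORAL,
   Per-Class CORAL, subspace alignment, and MMD-penalized joint training
   (deep domain confusion) are implemented behind a common benchmark.
2. **Can we predict transfer success without running the transfer?**  Six
   transferability measures — LEEP, H-score, hypothesis margin,
   cross-dataset silhouette, TDAS, and MMD — are computed on training data
   only and correlated with held-out accuracy.

## Adaptation algorithms

### CORAL

Correlation alignment seeks a linear map `A` on zero-meaned source features
minimizing `||A' C_s A - C_t||_F^2`, where `C_s`, `C_t` are the source and
target feature covariances.  The closed-form optimum whitens the source and
recolours with the target:

    A* = (U_s S_s^{+1/2} U_s') (U_t[1:r] S_t[1:r]^{1/2} U_t[1:r]')

with `S^{+1/2}` the square root of the Moore–Penrose pseudoinverse,
`U_t[1:r]` the top-`r` eigenvectors of `C_t`, and
`r = min(rank C_s, rank C_t)`.  All matrix functions go through one
symmetric eigendecomposition routine with a single global relative rank
threshold of `1e-10` on singular values, so `r` is reproducible.

Two conventions deserve note:

* **Shrinkage.** The raw covariance estimator adds nothing; inside
  `fit_coral()` a default ridge of `1e-6 * trace(C)/d` per side guards the
  whitening inverse on near-singular activations.  `shrinkage = 0` exposes
  the pure pseudoinverse/truncation path.
* **Re-centering.** The objective constrains covariances only.
  `recenter = "none"` leaves the transformed source zero-meaned (the
  literal objective); `recenter = "target"` adds the target mean back.
  The benchmark harness uses `"target"` because a classifier trained on
  pooled source + target data is sensitive to a mean offset between the two
  clouds; both behaviours are exposed since neither is canonical.

**Per-Class CORAL** fits one `A_i` per class, aligning the class-conditional
covariances, and transforms each source class with its own matrix (with the
class-specific means used for centering).  Classes absent from either side
or with fewer than `min_class_n = d + 2` samples per side fall back to the
global transform — below `d + 2` the class covariance is necessarily
singular.  With a single class the procedure reproduces plain CORAL bit for
bit.

### Subspace alignment

Both domains are projected onto their top-`k` PCA subspaces (`k = 100` by
default, truncated to the data rank with a warning) and the source basis is
aligned to the target basis by `M = V_s' V_t`.  Source samples map to
`x V_s M`, target samples to `x V_t`.  Centering is internal to the basis
*fit*; samples are projected raw.  This matters for TDAS (below): with
centered projections a pure translation of the target would be invisible to
the similarity.

Subspace alignment aligns *bases*, not sample points.  At full rank
`V_s M = V_t` exactly, i.e. the source is simply re-expressed in the target
basis; a rotated copy of a dataset therefore does not reproduce its own
coordinates pointwise, but the coordinate covariance spectra agree.  PCA
columns are sign-fixed (largest-magnitude loading positive) so fits are
deterministic; all quantities derived from `M` are invariant to those sign
choices.

### Head re-training and the DDC reference trainer

The "head" stands for the single dense layer adjacent to the output of a
frozen network: a multinomial logistic classifier (`nnet::multinom`) with
L2 weight decay `10^-6.9`, the regularization used for pre-training the
reference network; fits are deterministic given a seed.

`ddc_reference_train()` is a compact, self-contained implementation of
MMD-penalized joint training: a one-hidden-layer tanh network trained by
Adam (learning rate 0.001) on paired source/target mini-batches, with loss

    cross-entropy(source batch + target batch) + lambda * MMD^2(H_s, H_t)

where `H_s`, `H_t` are the hidden activations of the two half-batches.  The
RBF-MMD gradient is analytic; the per-batch bandwidth comes from the median
heuristic on the pooled batch activations and is treated as a constant with
respect to the gradient (re-deriving the bandwidth each batch, rather than
freezing a global one, follows the estimator's i.i.d.-batch reading; the
choice is exposed only through the reported traces).  The default estimator
inside batches is the linear-time unbiased one; per-batch values therefore
fluctuate around the true discrepancy and only their average is
interpretable.  The reported `final_mmd2` is the quadratic-estimator MMD of
the full-dataset hidden activations after training.

## Transferability measures

* **LEEP** builds an empirical Bayes classifier from the posteriors
  `theta(x)_z` of a source-trained model on target samples:
  `P(y|z) = P(y,z)/P(z)` with `P(y,z)` the average posterior mass samples
  of true class `y` put on source label `z`.  LEEP is the mean
  `log sum_z P(y_i|z) theta_iz`; it is 0 only for a perfect one-hot
  predictor and `log(1/2)` for uniform posteriors on balanced binary
  labels.  Logs are guarded at `1e-300`.
* **H-score** is `tr(cov(phi)^{-1} cov(E[phi|Y]))` with *population* (1/n)
  covariances and class-frequency weights on the conditional means — the
  normalization under which the law of total covariance holds and the
  two-point, zero-within-variance construction scores exactly 1.  The
  pseudoinverse is used by default; with a full-rank covariance and the
  plain inverse the score is invariant under any invertible linear map of
  the features.
* **Hypothesis margin** and **cross-dataset silhouette** treat *dataset
  membership* (source vs target) as the class; sleep-stage labels are
  ignored.  The margin of a point is half the difference between its
  nearest-miss distance (other dataset) and nearest-hit distance (own
  dataset, excluding itself), averaged over the union.  Both sets are
  stride-downsampled by a factor of 10 (seeded circular offset) before the
  quadratic-cost distance computation; `downsample = 1` disables this.
  The silhouette uses the classic orientation `(b - a)/max(a, b)` — +1 for
  well-separated domains — since the alternative sign flips the meaning of
  every separation limit; points with `a = b = 0` contribute 0.
* **TDAS** (target density around source) counts, per source sample, the
  target samples whose aligned-subspace similarity
  `sim(x_s, x_t) = (x_s V_s M) . (x_t V_t)` reaches `eps`, and averages the
  counts.  `eps` is the median pairwise Euclidean distance within the
  target, scaled by 0.1, 1 or 10.  The dot-product similarity is compared
  against the distance-derived threshold exactly as defined — the unit
  mismatch is deliberate and no normalization is silently added.
* **MMD** as a measure is the quadratic-estimator squared maximum mean
  discrepancy under an RBF kernel, bandwidth from the median heuristic on
  the pooled data (`gamma = scale/(2M)` with `M` the median *squared*
  pairwise distance; scales 0.1/1/10 probe sensitivity).  The quadratic
  estimator is the biased V-statistic (diagonals kept), nonnegative by
  construction; the linear-time estimator pairs consecutive samples of a
  seeded shuffle, is unbiased, and may be slightly negative.

## The synthetic study family

Real wearable-EEG feature sets are not redistributable, so every test and
the acceptance script run on a synthetic family built to emulate the study
design of a wearable staging cohort: **24 subjects, 1–6 recordings each**
per domain by default, an N2-dominant stage prior
(Wake .17, N1 .05, N2 .45, N3 .13, REM .20 — conventional values, not
estimates), per-subject Gaussian mean offsets (sd 0.3), and class-conditional
isotropic Gaussian features (`d = 10`, within-class sd 1) whose means sit on
a positive activation baseline (1.5 per dimension), as post-ReLU activations
do.

The **domain shift** knob models a lower-SNR sensor as *signal
attenuation*: target class means are scaled by a gain
`g = max(0, 1 - shift * within_sd / (baseline * sqrt(d)))`, which displaces
the grand activation mean by exactly `shift * within_sd` and shrinks the
between-class structure by the same factor while the noise floor stays
fixed.  This choice was deliberate: an additive displacement along a random
direction leaves a raw-dot-product similarity like TDAS insensitive (or
even increasing, through a variance effect) and can transiently *help* a
fixed classifier for some geometries, whereas attenuation degrades class
separability monotonically for any seed — which is what a weaker sensor
does.  A separate `rotation_angle` rotates target means in a seeded
2-plane, and `cov_scale` inflates target noise.

`class_mean_spread = 0.7` was calibrated once so that a source-trained head
reaches roughly 78% target accuracy at zero shift — the accuracy regime of
single-channel wearable staging — and not revisited.  Default
`epochs_per_recording = 120` keeps a default simulation light; a real night
has several times more epochs, which changes estimator variance but not the
generative structure.

What the generator does **not** emulate: stage-transition temporal
structure (epochs are i.i.d. given the subject), non-Gaussian activation
distributions, per-subject covariance changes, and label noise.  Passing
monotonicity and correlation checks on this family shows the estimators
and the harness behave as designed — not that any particular algorithm will
win on a given real cohort.

## Benchmark protocol

`loso_benchmark()` runs leave-one-subject-out cross-validation on the
target: for each held-out subject, each algorithm trains on the source
(balanced, see below) plus the remaining target subjects, and is scored on
the held-out subject (accuracy and Cohen's kappa).  Transferability
measures are computed per fold on the training portion only — never on the
held-out subject.  Aggregation reports per-algorithm mean ± sd, the
fraction of folds each algorithm wins (exact ties split the win equally),
a two-sided paired t-test of each algorithm against the head-retraining
baseline (a zero-variance difference is reported as an explicit error, not
a silent 0), and Spearman correlations (average ranks for ties, two-sided
t-approximation p-values) of every measure with fold accuracy — per
algorithm and pooled "overall" across algorithms, with optional Bonferroni
flags whose family size defaults to the number of correlation cells.

**Source balancing**: when an algorithm trains on both domains, the source
is reduced to its first recording per subject, then every n-th recording
with `n = floor(#source recordings / #target recordings)` — keeping the
subset representative without biasing toward multi-recording subjects.

Per-fold seeds derive from the run seed through a Lehmer-style mixing map
that keeps every derived seed inside the 32-bit integer range.

## Numerical conventions

* Global relative rank threshold `1e-10 * sigma_max` for every rank
  decision (covariances, PCA, pseudoinverses).
* PCA sign convention: largest-magnitude loading positive.
* Covariance estimators: unbiased 1/(n-1) in `empirical_covariance()`;
  population 1/n inside H-score (see above).  One sample yields
  `shrinkage * I`.
* The linear-time MMD shuffles each set from the *same* seed, so identical
  sets receive identical orderings and the estimator cancels exactly.
* Hypothesis-margin downsampling is a deterministic stride with a seeded
  circular offset applied to each set independently.
* `kappa` with both raters constant on the same class is 1; Spearman with
  zero rank variance and paired t-tests with zero-variance differences
  raise informative errors.

## Problem sizes

The test suite and the acceptance script use desk-scale instances chosen as
package defaults: 20 random 5-dimensional, 500-sample instances for the
CORAL optimality check; 1000 seeded replicates at n = 100/side (against 50
quadratic replicates at n = 2000/side) for the linear-MMD unbiasedness
check; a shift family of 10 subjects × 1 recording × 100 epochs
(1000 samples/side) over shifts {0, 0.5, 1, 2, 4}; twenty 4-subject LOSO
benchmark runs for the correlation structure; and ten paired seeds for the
DDC mechanism check.

## Known limitations

* The DDC trainer is a reference implementation on a small dense network;
  it demonstrates the mechanism (the penalty shrinks hidden-layer MMD) but
  is not a convolutional sleep stager.
* TDAS inherits the unit mismatch of its definition; its absolute value is
  only comparable between datasets with similar projection scales.
* LEEP requires externally supplied posteriors; the harness produces them
  from a multinomial head trained on source features, not from a deep
  model.
* With very small target cohorts the paired t-test over folds has few
  degrees of freedom; the harness reports it but draws no conclusion.
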