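---
title: "Density features for myoelectric movement classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density features for myoelectric movement classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdemg)
```

This vignette documents the statistical machinery in `kdemg`, the
assumptions behind it, and the design decisions taken where a choice was
genuinely open. It states no empirical result beyond what the package's
test suite and `scripts/acceptance.R` themselves compute.

## Signal model and preprocessing

A recording session yields, per movement repetition, a channels-by-time
matrix sampled at `fs` Hz (`emg_record`). Preprocessing follows the
standard myoelectric chain:

1. **Band-pass filtering.** Butterworth, applied forward–backward
   (`signal::filtfilt`), so the output is zero-phase: features computed on
   a window are never delayed relative to the movement labels. The filter
   order argument refers to the overall band-pass order (an order-4
   band-pass is `signal::butter(2, ...)`). Conventional-control material
   uses 20–500 Hz at order 4; the simultaneous protocol uses 5–500 Hz at
   order 8.
2. **Standardization.** Channels are brought to zero mean and unit sample
   standard deviation (n − 1 denominator). Two variants exist:
   `standardize_channels()` for a single record, and
   `standardize_dataset()`, which pools the mean and standard deviation
   per subject-channel across all records — the transform one gets when
   the *continuous* session recording is standardized before segmentation.
   The pipeline drivers use the pooled variant: per-record standardization
   would equalize every movement's amplitude and destroy the very
   between-movement amplitude structure the features rely on.
3. **Outlier removal.** The 3-sigma rule, one pass, no re-estimation of
   the standard deviation after removal. Because channels may lose
   different numbers of samples, the rule is applied per channel-window
   during feature extraction (densities do not need aligned channels), and
   `remove_outliers_3sigma()` returns a ragged per-channel container when
   called on a whole record.
4. **Windowing.** `window_spec(width_ms, step_ms)` with the count formula
   `floor((T − W)/S) + 1`. A stated overlap is converted by the caller:
   "400 ms windows with 100 ms overlap" is `window_spec(400, 300)`;
   "160 ms windows with 40 ms increment" is `window_spec(160, 40)`. Both
   readings are explicit in the API so either convention is reproducible.
5. **Middle third.** The offline analysis estimates densities over the
   central third of each contraction (onset and offset transients carry
   label noise). Boundaries follow a floor convention: samples
   `floor(n/3)+1 … floor(2n/3)`. The sequential driver then windows this
   middle third with 400/300 ms sliding windows, giving the learners
   several rows per repetition; the un-windowed variant (one density per
   repetition) is available through `window_spec(mode = "whole")`.

## Density estimation

`kde_diffusion()` implements the adaptive estimator whose bandwidth is
selected through the smoothing properties of a linear diffusion: bin the
data on a uniform grid over the data range extended by 10% per side,
cosine-transform, solve the fixed-point equation for the optimal squared
diffusion time `t*` (the plug-in functional is evaluated top-down from the
7th stage, so no normal-reference rule enters), damp the coefficients by
`exp(−k²π²t*/2)`, and invert. Numerical choices:

* the grid is a power of two (transform-based smoothing); the standalone
  estimator defaults to 2^12 points, feature extraction to 512 (see below);
* the root is bracketed starting from a sample-size-dependent upper bound
  doubled up to 0.1; tolerance 1e−9, at most 50 bracket expansions; if no
  root is bracketed, the |f| minimizer is accepted; failing that the
  estimator falls back to a normal-reference bandwidth with a classed
  warning (`kdemg_warning_bandwidth_fallback`);
* negative ringing from the inverse transform is clipped to zero.

`kde_gaussian_fixed()` is the textbook fixed-bandwidth estimator used for
cross-checks. Density derivatives use the closed form of the Gaussian
kernel's derivatives, `K⁽ʳ⁾(u) = (−1)ʳ Hᵣ(u) K(u)` with **probabilists'**
Hermite polynomials (`H₁(x) = x`, `H₂(x) = x² − 1`). This convention makes
the r = 1 estimate the exact analytic derivative of the fixed-bandwidth
density estimate, which the test suite verifies against central finite
differences. First-order and three-point difference operators
(`derivative_difference()`) are provided as the cheap alternatives; the
three-point operator equals the average of consecutive first-order
differences exactly.

## The three features

Per channel-window the density is estimated once by diffusion KDE and all
features are read off the estimation grid (512 points by default):

* **TMD**: trimmed mean of the density values. Trimming is count-based —
  sort, drop `floor(p/100·n)` observations per tail, average the rest —
  which is deterministic under ties; defaults 5%/5%.
* **ED**: approximate entropy of the density value sequence ordered by
  abscissa. ApEn uses Chebyshev distance with self-matches included, so
  `Φ` terms are always finite; a constant sequence returns 0. Defaults
  `m = 2`, `r = 0.2·sd`, configurable via `apen_params()`. Because no
  tuned tolerance values are available for density sequences, a coarse
  bootstrap-stability tuner (`tune_apen()`, grid `m ∈ {1,2}`,
  `r ∈ {0.1, 0.15, 0.2, 0.25}·sd`) is provided, intended per subject.
* **TMAVDD**: trimmed mean of |f̂′| on the same grid, reusing the
  diffusion bandwidth (a separate plug-in bandwidth for the derivative
  would cost another selection step per window for little gain at these
  window lengths). Trimming parameters are shared with TMD.

Grid evaluation (rather than evaluation at the sample points) is used for
all three: it is what the transform-based estimator naturally returns, and
ApEn needs an ordered sequence — the abscissa ordering provides it. The
512-point default keeps the O(N²) ApEn scan (implemented in C++) at about
a quarter million pair comparisons per channel-window. Rows whose features
come out non-finite (e.g. a channel that is constant within a window) are
dropped with a classed warning, never imputed.

Comparison features: RMS, waveform length, mean absolute value, and
3-level sym4 wavelet band energies (D1, D2, D3, A3). No R wavelet package
is declared as a dependency; the transform is an in-package periodized
orthogonal filter bank with the sym4 taps frozen in source, so band
energies sum exactly to signal energy — a property the tests check along
with an independent full-convolution oracle.

## Feature selection

CFS scores a subset S of k features by
`Merit(S) = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)`. The default correlation
measure is symmetric uncertainty after equal-frequency discretization into
10 bins (identical values always share a bin, so a feature that relabels
the class reaches SU = 1); absolute Pearson correlation with one-vs-rest
class encoding is available as `measure = "pearson_abs"`. Constant
features get zero correlations with a warning.

The search is best-first from the empty set: all single-feature expansions
are generated, the best unexpanded subset (ties broken lexicographically
by feature names, making the search deterministic) is fully expanded, and
the search stops after five consecutive fully expanded non-improving
subsets (`max_stale = 5`, exposed). A safety cap on expansions exists for
pathological landscapes. On small problems the tests require the search to
recover the exhaustive-search optimum.

## Classification and fusion

* **LDA** (`MASS::lda`) — posteriors from the fitted discriminants.
* **SVM** — RBF kernel (`e1071::svm`) with probability outputs. The cost
  and kernel width come from a seeded stratified 3-fold grid search over
  `C ∈ {0.1, 1, 10, 100}` × `γ ∈ {0.01, 0.1, 1, 10}` on the training
  split; with classes too small to stratify, training accuracy is the
  criterion. The first-best combination is taken, preferring low cost.
* **MLP** (`nnet::nnet`) — one hidden layer of 15 units, softmax outputs
  trained by BFGS with weight decay 1e−4, seeded. `nnet`'s hidden
  activation is the logistic sigmoid; a tanh-hidden variant is not
  available in the underlying library, and at this layer width the choice
  affects only the parameterization, not the family of decision surfaces.
* **BKS fusion** — every training row is indexed by the tuple of the three
  learners' decisions; each cell stores the counts of true classes seen
  with that tuple, and prediction returns the cell's majority class.
  Unseen tuples and tied cells fall back to the class with the highest
  mean posterior across learners. By construction BKS is the empirical
  Bayes rule over decision tuples, so on the training distribution it
  cannot be worse than any single learner — a property the tests verify.
  By default all learners see the full CFS-selected subset;
  `train_base_learners(features = ...)` accepts any subset, so a seeded
  random partition of features across learners is a one-liner if desired.
* **Boosted trees** (`xgboost`) for the 9-class simultaneous task: 600
  trees, maximum depth 18, learning rate 0.1, histogram method, single
  thread, seeded — deterministic given the seed.

## Evaluation

`metrics_report()` derives per-class TP/TN/FP/FN and
precision/recall/accuracy/F, plus macro-F, micro precision/recall/F and
overall accuracy. Micro-F equals pooled precision, pooled recall and
overall accuracy in single-label multi-class scoring; the tests assert
this identity to 1e−12 on a thousand random confusion matrices. When a
class has no true positives its F-score is undefined; macro-F is then NaN
by design (no zero-substitution), and the per-movement misclassification
table plays the role of the complementary "ideally classified movements"
view: a movement counts as misclassified in a (split, repetition) when any
of its windows errs in either direction (FN or FP) — repetition-level
counting.

Split schemes: the repeated hold-out over six repetitions is fixed
verbatim — test sets {1,4}, {2,5}, {3,6} — and `make_kfold()` provides
seeded stratified k-fold with per-class near-equal and globally balanced
folds. Fleiss' kappa (with the large-sample chance-agreement CI) and
McNemar's test (exact binomial below 25 discordant pairs, continuity-
corrected chi-square above; p = 1 with no discordant pairs) cover the
agreement statistics.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of a
conventional-control acquisition: per class, a per-channel plateau
amplitude vector (uniform on 1–4 by default) and a spectral sub-band
inside 20–450 Hz are drawn once from `profile_seed`; each repetition is
unit-variance band-limited Gaussian noise scaled by the amplitude profile
under a trapezoidal envelope (10% ramps), plus white sensor noise at
`snr_db` (20 dB default). Defaults mirror the protocol the pipeline
targets: 2 ksps, 5 s contractions, 3 s rests, 6 repetitions.
`generate_simultaneous_dataset()` produces the 9-class two-degree-of-
freedom protocol (4 singles, 4 valid pairs, rest) at 8 channels / 1.2
ksps, 4 × 3 s repetitions; combined classes superpose independent
realizations of the two component profiles, so their channel power is
approximately the sum of the components'.

What the generator deliberately does *not* model: motor-unit action
potential shapes and recruitment, electrode shift, inter-subject
variability, non-stationarity within a contraction, crosstalk structure
beyond the shared envelope, and the heavy-tailed amplitude distributions
of some real recordings (a Laplace-amplitude variant can be emulated by
transforming the generator output, and KDE features make no Gaussian
assumption). Passing pipeline tests on this material therefore shows the
machinery is correct and well-calibrated, not that the features reach any
particular accuracy on real recordings.

The two seed streams are independent, so class geometry can be held fixed
while resampling noise. All drivers derive every stochastic component
(generator, SVM search and calibration, MLP initialization, fold
assignment, boosting) from their single `seed` argument; re-running with
the same seed reproduces all metrics bit-for-bit.

## Problem sizes and runtime choices

The stock experiment configurations are desk-scale: the sequential run
uses 10 classes × 8 channels × 6 repetitions (300 windows of 800 samples;
about 2,400 density estimates), the simultaneous run 9 classes × 4
repetitions at 160/40 ms windows (about 2,600 windows × 8 channels), and
the online sweep epochs of 300/200/100/50 ms over the middle third. The
512-point feature grid and the C++ ApEn inner loop keep a full
channel-window's features at a few milliseconds.

## Known limitations

* The diffusion bandwidth assumes a univariate, reasonably smooth density;
  windows shorter than ~30 samples are rejected rather than estimated.
* ED on the density grid measures the regularity of the density *curve*,
  not of the time series; its discriminative value is empirical.
* BKS tables grow with the number of distinct decision tuples; with many
  classes and few training rows most test tuples are unseen and the
  posterior fallback dominates — fusion then degrades gracefully toward
  mean-posterior voting.
* LDA requires the pooled within-class covariance to be invertible; with
  very few rows per class, select fewer features (CFS usually does).
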