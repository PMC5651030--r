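---
title: "Methods: connectome-convolutional classification, its benchmark and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-convolutional classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccnn)
```

This vignette documents the models implemented in `ccnn`, the design of the
simulated benchmark, and every numerical choice a user may want to audit.
Code chunks are illustrative and not evaluated at build time; all empirical
claims made here are the ones computed by the package's test suite and by
`scripts/acceptance.R`.

## 1. The classification problem

The input is a set of labelled connectomes: symmetric N × N matrices whose
entry (i, j) quantifies the connectivity between ROIs i and j under some
metric. A *channel* is one metric's full matrix; several channels (e.g. DTW
distance and warping path length) can be stacked, exactly like the colour
channels of an image. The task is two-class discrimination (e.g. patients
vs. controls, or perturbed vs. unperturbed simulated connectomes).

Three architectures are provided through `model_config()` / `build_model()`:

| kind | input | layers | optimizer |
|------|-------|--------|-----------|
| `ccnn` | C × N × N matrices | conv 64 × (C×1×N) → conv 128 × (64×N×1) → dense 96 (ReLU, dropout) → softmax 2 | Adam |
| `simple` | F = C·N(N−1)/2 upper-triangle features | dense 128 (sigmoid) → softmax 2 | SGD |
| `deep` | same F features | dense 128 (ReLU) → dense 96 (ReLU, dropout) → softmax 2 | Adam |

The CCNN's first layer slides a filter spanning one *entire row* (all
channels) down the N rows of the matrix: each ROI's connectivity
fingerprint receives 64 learned summary features. The second layer
collapses the ROI axis, producing 128 features per connectome, roughly
matched to the instance counts (~150) these models are designed for. Row
convolution is what makes the parameter count grow by only C·N·64 when a
channel is added, while the dense baselines grow by N(N−1)/2·128; both
facts are asserted by the test suite at N = 499 against the published
counts (4,132,224 / 4,164,160 / 15,904,384 / 15,916,608 weights).

All forward/backward passes are expressed as dense BLAS products (the conv
layers are, per instance, an N × (C·N) design matrix times the filter
bank), so no deep-learning framework is required.

### Training defaults and why

* **Optimizer**: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) for `ccnn`/`deep`;
  plain minibatch SGD for `simple`. Learning rates default to Adam's
  canonical 1e-3 and 0.05 for SGD. We deliberately use the standard Adam
  step size: with much smaller steps the cumulative movement of the first
  convolutional layer stays on the order of its random initialization,
  which destroys the weight-based interpretation of §4 while barely
  changing classification accuracy.
* **Dropout**: inverted dropout, keep probability 0.6, applied only to the
  96-unit dense layer of `ccnn`/`deep`; the simple net has none.
* **Epochs / early stopping**: at most 200 epochs, batch size 16, stopping
  once the epoch loss has not improved by `min_delta = 1e-4` for
  `patience = 15` epochs. On the benchmark tasks this typically stops
  around 30–50 epochs.
* **Initialization**: seeded truncated normal (±2 sd), sd =
  min(0.05, 1/√fan-in), biases zero. The 0.05 cap matters at small N:
  without it the summed-|weight| ROI profiles are dominated by
  initialization mass rather than learned structure.
* **Standardization**: optional per-channel z-scoring of matrix entries
  with statistics computed on the training fold only and reused at
  inference (`standardize`, default on for multi-channel inputs, where
  metrics of different scales are mixed).
* **Determinism**: `config$seed` drives initialization, batch shuffling and
  dropout through an isolated RNG stream; identical seeds give bitwise
  identical trained weights.
* **Degenerate inputs**: single-class training sets, shape mismatches with
  the config, and empty index vectors are errors, not warnings.

## 2. The simulated benchmark

`generate_base_pair()` + `simulate_dataset()` emulate a controlled
two-class study:

1. Two correlation-structured base connectomes ("healthy" and an
   "alternative" playing the patient role) are synthesized as correlation
   matrices of latent-factor signals (about one factor per ten ROIs plus
   unit idiosyncratic noise). This forces the statistical shape of a real
   functional connectome — symmetry, unit diagonal, entries in [−1, 1],
   positive semidefiniteness — without requiring any real data.
2. The class-1 template replaces the rows *and* columns of m selected ROIs
   of the healthy connectome with the alternative's
   (`replace_roi_fingerprints()`); intersections of two replaced
   fingerprints take donor values and the result stays symmetric. The
   selected indices are recorded as ground truth. Benchmark settings use
   m ∈ {1, 5, 10}.
3. Each of the 75 + 75 replicas receives independent additive noise
   `w · S`, where S is a Gaussian matrix symmetrized as A + Aᵀ and divided
   by its maximum absolute entry (so max |S| = 1 exactly), and the weight w
   sweeps 1…10.

Decisions worth flagging:

* **Noise SD.** Entries of A + Aᵀ have sd √2 before normalization; the
  realized post-normalization sd therefore depends on N through the
  extreme value of ~N²/2 Gaussians (≈ √2 divided by max|A + Aᵀ|). We
  implement the construction literally (symmetrize, then max-abs
  normalize) rather than forcing any particular sd value.
* **Diagonal and clipping.** The noise diagonal (2·A_ii before
  normalization) is kept, and noisy entries may leave [−1, 1]; neither
  clipping nor re-normalization is applied. Classifiers do not require
  bounded inputs, and symmetry is the only structural constraint the
  replica construction must preserve.
* **Independence.** Noise is drawn independently per replica; paired
  healthy/modified replicas do not share a noise realization.
* **What is *not* emulated**: BOLD time series with hemodynamics, subject
  structure (each simulated instance is its own group), atlas geometry,
  site/scanner effects, and class imbalance. Perfect accuracy on this
  benchmark therefore demonstrates the architecture's capacity to detect
  fingerprint perturbations under additive symmetric noise — not clinical
  performance.

## 3. Connectivity metrics

`pearson_matrix()` is the standard correlation matrix (delegated to
`stats::cor`; zero-variance signals are an error naming the ROI).

`dtw_pair()` / `dtw_matrices()` implement exact dynamic-programming DTW
with the step set {(1,0), (0,1), (1,1)} inside a Sakoe–Chiba band of
half-width `window_radius` (default ⌈T/10⌉ samples; `T − 1` removes the
constraint). Defaults: series are z-scored first (`znormalize = TRUE`), the
local cost is the absolute difference, and the reported distance is the
raw accumulated cost without path-length normalization. The warping path is
recovered by backtracking with diagonal-preferred tie-breaking — among
equal-cost predecessors the diagonal wins, then the vertical — which makes
the reported path length deterministic and minimal among ties in the
common cases. Both the raw path length L (T ≤ L ≤ 2T − 1) and the relative
form (L − T)/T (zero on the diagonal of a matrix, invariant to T) are
available; the relative form is the default matrix channel. Degenerate
inputs: unequal lengths, constant series under z-scoring, and radii > T − 1
are errors. Correctness is established in the tests against two
independent oracles: a memoized recursion over the full alignment lattice
(T ≤ 12) and exhaustive enumeration of every monotone path (T ≤ 6),
plus monotonicity of the distance in the band radius.

## 4. Interpretation of the first layer

`roi_importance()` sums the absolute conv1 weights per ROI over the 64
filters (and per filter over ROIs), per channel, never silently pooled.
`recovery_score()` counts how many ground-truth modified ROIs appear in
the top-k of that ranking. Two caveats are inherent to the method: a ROI
with small first-layer mass can still matter (filter outputs are
re-weighted downstream), and the profile's contrast depends on the trained
weights dominating the initialization — hence the capped init sd and the
standard Adam step discussed in §1. For interpretation runs the model is
trained on the whole dataset, since no generalization estimate is needed.

## 5. Evaluation machinery

* **Folds**: `make_fold_plan()` shuffles distinct group IDs under a seed
  and deals them round-robin, so all measurements of a subject share a
  fold; with singleton groups this is plain k-fold. No class
  stratification is applied.
* **Scores**: accuracy and AUC are *pooled* over the out-of-fold
  predictions of all instances (consistent with instance-count binomial
  reasoning), not averaged over folds; per-fold accuracies are also
  reported. AUC is the rank-based (Mann–Whitney) statistic with ties
  counted ½, applied to the positive-class softmax output.
* **Chance level**: `chance_baseline(n)` returns the smallest k with
  F_Binom(n, k, 0.5) ≥ 0.95 and the baseline accuracy k/n. This
  "smallest-k" formalization reproduces the standard printed thresholds
  56.67% (n = 150, k = 85) and 56.85% (n = 146, k = 83) exactly. (At
  n = 150 the CDF at k is 0.957; at n = 146 it is 0.959.)
* **Comparing classifiers**: `compare_classifiers()` is an exact two-sided
  binomial test at p = ½ restricted to discordant instances (McNemar-style
  exact test), returning 1 when the classifiers agree everywhere.

## 6. Problem sizes used in the shipped runs

The published full-scale setting (499 ROIs) is used for everything
analytic — parameter counting and feature vectorization — where it costs
nothing. For runs that train networks, this package's tests and
`scripts/acceptance.R` use scaled-down simulated datasets chosen once as
realistic desk-scale versions of the same protocol: 150 instances and
10-fold CV throughout; N = 100 ROIs for the acceptance benchmark (10
modified ROIs, noise weight 1) and the recovery experiment (5 modified
ROIs, noise weight 5, five seeded full-data trainings); N = 60 for the
in-suite accuracy check; N = 30–50 for smoke and property tests. A 7-fold
grouped protocol over 49 synthetic subjects with 146 measurements
exercises the subject-grouped machinery.

## 7. Known limitations

* At desk-scale N the dense baselines own far fewer parameters than at
  N = 499, so the overfitting pressure that separates the CCNN from the
  deep network at full scale is much weaker: in the moderate-noise
  comparison the three models' accuracies can tie, and the checked
  property is the ordering CCNN ≥ deep ≥ simple rather than a margin.
* The synthetic base pair is *not* a fitted model of real resting-state
  connectomes; between-class effect sizes depend on the latent-factor
  draw. Absolute accuracies on the benchmark should be read relative to
  the chance threshold, not as predictions of real-data accuracy.
* The simple network at full scale (15.9M weights into a sigmoid layer)
  trains slowly under plain SGD; this matches its role as a weak matched
  baseline rather than a recommended model.
* Multi-class heads are wired (softmax over `n_classes`) but only the
  two-class path is exercised by tests.
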