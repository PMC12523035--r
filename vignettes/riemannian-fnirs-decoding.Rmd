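---
title: "Riemannian decoding of dual-chromophore fNIRS: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian decoding of dual-chromophore fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Functional near-infrared spectroscopy (fNIRS) records two anticorrelated
hemoglobin signals — oxygenated (HbO) and deoxygenated (HbR) — over a few
dozen scalp channels. Classifying the mental task a participant performs
from a single trial is hard with per-channel summary statistics because
much of the task information sits in *how channels co-activate*, not in any
single channel's amplitude.

`riemnirs` therefore represents each trial by a channel-by-channel kernel
or covariance matrix per chromophore. Such matrices are symmetric
positive-definite (SPD) and live on a curved manifold; treating them with
Euclidean operations (averaging entries, subtracting matrices) distorts
their geometry. All operations here use the affine-invariant Riemannian
metric (AIRM),

$$ d(A, B) = \lVert \log (A^{-1/2} B A^{-1/2}) \rVert_F , $$

whose key property is congruence invariance: any invertible linear remixing
$G$ of the channels, $S \mapsto G S G^\top$, leaves all distances — and
hence all classifier decisions — unchanged.

The package's central feature construction is the block-diagonal **super
kernel**

$$ K_{\mathrm{block}} = K^{\mathrm{HbO}} \oplus K^{\mathrm{HbR}}, $$

where each block is estimated with its own kernel function and its own
shrinkage intensity. Setting the cross-chromophore entries to zero
restricts the feature to a product manifold: for 62 channels per
chromophore the full $124 \times 124$ SPD manifold has
$124 \cdot 125 / 2 = 7750$ dimensions, while the two-block manifold has
$2 \cdot 62 \cdot 63 / 2 = 3906$. The lower-dimensional representation
discards cross-chromophore terms (which carry little independent
information when HbR is largely an anticorrelated copy of HbO) and lets the
two chromophores be tuned independently.

Two classifiers operate on these features:

* **TLR** — tangent-space logistic regression: all matrices are mapped to
  the tangent space at the Fréchet (geometric) mean of the training set,
  where the manifold is locally Euclidean, and an L2-penalized multinomial
  logistic regression is fitted on the vectorized tangent images.
* **RSVC** — a support vector classifier on the precomputed Gram matrix of
  tangent-space inner products, one-vs-rest for more than two classes.

Crossing five feature constructions (super kernel SK, block kernel BK,
block covariance with shared/individual shrinkage BC/BCI, full matrix C)
with the two classifiers gives ten Riemannian models; four traditional
baselines (LDA, logistic regression, RBF-SVC, random forest) operate on
per-channel summary features (mean, variance, peak, zero crossings, skew,
kurtosis).

## Kernel estimators and shrinkage

Twelve estimators are exposed under their conventional short names:
`corr`, `cov`/`scm` (centered sample covariance, $1/t$ normalization),
`lwf`, `oas`, `sch` (covariance shrunk toward the scaled identity with the
Ledoit–Wolf, oracle-approximating, and Schäfer–Strimmer analytic
intensities), `hub`, `tyl` (Huber and Tyler M-estimators; Tyler
trace-normalized to the channel count), and the pairwise kernels `poly`,
`rbf`, `laplacian`, `cosine`.

Choices a user should know about:

* **Centering.** Covariance-type estimators center each channel first; the
  nonlinear kernels act on the rows as given. After whole-recording
  z-scoring the channel means are already near zero, so this choice is
  low-impact, but it matches the conventional behavior of the libraries
  these estimator names come from.
* **Kernel hyperparameters.** `gamma = 1/t` for `rbf`/`laplacian`/`poly`,
  polynomial degree 3, offset 1 — the conventional defaults.
* **Huber tuning.** Clean fraction 0.9 (samples with squared Mahalanobis
  distance beyond the 0.9 chi-square quantile are downweighted),
  fixed-point tolerance 1e-6, at most 100 iterations.
* **Shrinkage target.** `shrink(K, alpha)` blends toward
  $\mu I$ with $\mu = \mathrm{tr}(K)/c$, preserving each block's overall
  scale while guaranteeing positive definiteness for any `alpha > 0`
  whenever the trace is positive.
* **PSD repair.** An estimator returning an eigenvalue below
  $-10^{-10}\lambda_{\max}$ raises an error (a broken estimator, not
  rounding); tiny negative eigenvalues above that bound are clipped to
  zero before shrinkage.

## Numerical choices on the manifold

* Matrix powers, logs, and exponentials go through the symmetric
  eigendecomposition, with an eigenvalue floor of 1e-12 for fractional and
  negative powers; inputs failing the floor raise rather than being
  silently clipped.
* The Fréchet mean uses the fixed-point iteration
  $M \leftarrow M^{1/2}\exp\!\big(\tfrac{s}{n}\sum_i \log(M^{-1/2} M_i
  M^{-1/2})\big)M^{1/2}$, initialized at the arithmetic mean and stopped
  when the tangent-mean norm drops below `tol` (default 1e-8, at most
  `max_iter` iterations). The classical unit-step iteration can enter a
  2-cycle when the inputs are widely spread — short 34-sample epochs yield
  shrunk covariances with condition numbers around $10^3$, where we
  observed exactly this — so the step $s$ is halved whenever the
  tangent-mean norm stops decreasing. When the plain iteration converges
  the safeguard never activates and the two procedures coincide.
* Tangent vectors take the upper triangle row-major with off-diagonal
  entries scaled by $\sqrt 2$, so Euclidean inner products equal Frobenius
  inner products and the vector norm of a tangent image equals the AIRM
  distance to the reference.
* Block-diagonal features carry their block sizes as an attribute; the
  classifier fits then compute Fréchet means and tangent maps per block.
  On a product manifold this is exact — the mean of block-diagonal
  matrices is block-diagonal — and it is what gives block models their
  3906-dimensional tangent space instead of 7750 (and roughly an 8-fold
  speedup at 62 channels).
* Ties in the exhaustive grid search resolve to the first configuration in
  grid order, making searches reproducible.

## The synthetic session generator

The study's recordings are not public, so the package ships a generator
whose defaults define the conditions under which everything is tested:

* **Design**: 8 tasks paired without replacement into 4 runs, two tasks
  alternating within a run, 12 trials per task per run (96 trials total),
  trial durations drawn uniformly from {5, 10, 15} s, 20 s rests, 60 s
  initial rest; 62 channels per chromophore at 3.47 Hz.
* **Task signal**: each task has one spatial loading (unit peak amplitude)
  driving an evoked response — a boxcar convolved with a double-gamma HRF
  (peak 6 s, undershoot 16 s) — plus a rank-2 stochastic *co-activation*
  component: two task-specific spatial patterns driven by band-limited
  random time courses under the same hemodynamic envelope. The
  co-activation component is the dominant task signature (`snr = 0.04`
  relative to unit-scale noise) while the evoked mean response is weaker
  (`evoked = 0.15` of the co-activation amplitude). This reflects the
  premise the method is built on — brain states differ in how channels
  co-fluctuate — while keeping channel means weakly informative, so
  traditional classifiers stay above chance without matching the
  covariance-based models. A per-trial lognormal gain (`gain_sd = 1`)
  models trial-to-trial hemodynamic variability.
* **HbO/HbR coupling**: the HbR task component is
  `hbr_scale * (1 - complementarity)` times the HbO component plus
  `complementarity` times an independent response with the task's own HbR
  patterns (`hbr_scale = -0.3`, `complementarity = 0.3`): anticorrelated
  but partially complementary.
* **Noise**: physiological sinusoids near 0.1 Hz (Mayer waves), 0.3 Hz
  (respiration), and 1.2 Hz (cardiac) with shared phases and per-channel
  amplitude jitter; 1/f and white components per channel; and a shared
  global nuisance component that the PCA regression stage is designed to
  remove.

The `snr` default was calibrated once, against a stated criterion: the
best covariance-based model's eight-choice cross-validation accuracy
should fall in the 0.6–0.8 range the study context reports, with
traditional baselines well below it, rather than everything saturating at
ceiling. It was then frozen.

What the generator does **not** emulate: optical physics (photon paths,
optode geometry, partial volume effects), motion artifacts and their
correction, cortical anatomy underlying the montage, or non-stationary
physiology. Passing tests on this generator therefore show that the
pipeline recovers co-activation structure of the assumed form from
realistic noise — not that any particular accuracy level transfers to real
recordings.

## Preprocessing

Fixed order: trim (5 s before the first onset to 15 s after the last
offset) → PCA global-component regression (channels as variables, first
component removed by least squares) → band filter → z-score → epoch. Every
stage can be bypassed.

* The high-pass is a zero-phase (forward–backward) Butterworth, order 2,
  0.01 Hz. The low-pass is Gaussian smoothing; "0.4 Hz" is interpreted as
  the half-amplitude cutoff of the Gaussian transfer function
  $e^{-2\pi^2\sigma^2 f^2}$, giving $\sigma = \sqrt{\ln 2 / 2} / (\pi
  \cdot 0.4\,\mathrm{Hz}) \approx 0.47$ s.
* z-scoring uses the population (1/N) standard deviation over the whole
  trimmed recording — not per epoch — so all trials share one scale.
* Epochs span cue onset to 10 s post-cue: `floor(10 × 3.47) = 34` samples,
  identical for 5, 10, and 15 s trials, so every kernel estimate uses the
  same amount of data. Onsets snap to the nearest sample.
* Conversion from raw optical densities to concentrations, spike removal,
  and motion correction are upstream concerns of acquisition software; the
  generator emits concentration-domain data directly.

## Evaluation machinery

* Repeated (default 5×) stratified 5-fold cross-validation; per-fold class
  counts deviate from perfect proportion by at most one; the model —
  including the tangent-space reference — is refitted per training fold.
* Permutation chance estimation shuffles labels at the trial level before
  fold construction and re-runs the full cross-validation; the p-value
  uses the add-one estimator $(1 + \#\{\text{null} \ge
  \text{observed}\})/(n_{\mathrm{perm}} + 1)$, which cannot return zero.
* Bootstrap (default 1000 resamples) percentile confidence intervals on
  cross-validation accuracies; paired t-tests with Cohen's
  $d = \bar{d}/s_d$ for model comparisons.
* The relative improvement score
  $\mathrm{RIS} = (A_{\mathrm{new}} - A_{\mathrm{base}})/(1 -
  A_{\mathrm{base}})$ normalizes gains by the headroom to perfect
  accuracy.
* The HbO-vs-HbR co-activation comparison computes per-task Fréchet-mean
  kernels per chromophore, all `choose(n_tasks, 2)` pairwise AIRM
  distances between task means, normalizes each distance vector to unit
  sum, and compares the two normalized vectors as empirical distributions
  on the real line with the 1-D Wasserstein distance (closed form via
  quantile functions). The alternative reading — histogram-binning the
  distance distributions first — is available via `normalize =
  "histogram"`. A one-sample t-test against zero aggregates
  per-participant statistics.

## Problem sizes used by the shipped checks

The package's own test suite and the acceptance script run entirely on
synthetic sessions at sizes chosen for a single CPU: chance-level recovery
uses a compact 6-channel montage (the permutation-null center is
channel-count-free), the model-ordering check uses 24 channels across 20
seeds with 5-fold single-repeat cross-validation, and the no-signal check
runs all fourteen models at 3-fold cross-validation with a reduced
permutation count. The full 62-channel default remains the generator's
study condition and is exercised directly by the examples above.

## Known limitations

* SNIRF (HDF5) import is not provided; sessions interchange through the
  package's epoch store (float64 matrices plus a JSON sidecar).
* The Fréchet mean is the only manifold optimization implemented; no
  Bures–Wasserstein or log-Euclidean user-facing metrics (log-Euclidean
  appears only as a test oracle for commuting cases).
* Bootstrap intervals are percentile, not BCa.
* The permutation and bootstrap machinery treats trials as exchangeable;
  temporal autocorrelation between neighboring trials of a run is not
  modeled.
* Traditional-model hyperparameter grids are configuration-driven; no
  attempt is made to reproduce any specific published grid.
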