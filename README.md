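# riemnirs

Riemannian-geometry classification of brain states from dual-chromophore
fNIRS recordings.

Functional near-infrared spectroscopy measures oxygenated (HbO) and
deoxygenated (HbR) hemoglobin over a few dozen scalp channels. Decoding
which mental task a participant performs from a single trial works poorly
with per-channel summary statistics, because much of the information is in
how channels *co-activate*. `riemnirs` represents each trial by
channel-by-channel kernel/covariance matrices — one per chromophore,
estimated with any of twelve registered estimators and regularized by
shrinkage toward a scaled identity — fused into a block-diagonal "super
kernel"

    K_block = K_HbO ⊕ K_HbR ,

a symmetric positive-definite (SPD) matrix classified on the SPD manifold
under the affine-invariant Riemannian metric

    d(A, B) = || log(A^{-1/2} B A^{-1/2}) ||_F .

Two Riemannian classifiers are provided — tangent-space logistic
regression (TLR) at the Fréchet mean of the training features, and a
support vector classifier on the tangent-space Gram matrix (RSVC) — across
five feature constructions (super kernel, block kernel, block covariance
with shared or individual shrinkage, full concatenated matrix), plus four
traditional baselines (LDA, logistic regression, RBF-SVC, random forest)
on per-channel summary features: fourteen models in all.

The package also ships:

* the full preprocessing chain (trimming, PCA global-component regression,
  Butterworth high-pass + Gaussian low-pass, z-scoring, fixed 10-s
  epoching at 3.47 Hz);
* a synthetic session generator emulating the eight-task, four-run,
  96-trial experimental design with task-specific spatial co-activation
  patterns, anticorrelated-but-complementary HbO/HbR, and physiological
  noise (Mayer waves, respiration, cardiac, 1/f, global nuisance);
* evaluation machinery: repeated stratified 5-fold cross-validation,
  permutation chance estimation, bootstrap confidence intervals, paired
  t-tests, the relative improvement score
  `RIS = (A_new - A_base) / (1 - A_base)`, and a 1-D Wasserstein
  comparison of HbO vs HbR pairwise-task distance profiles;
* a thin command-line interface (`inst/cli/riemnirs.R`) with `simulate`,
  `preprocess`, `fit`, `evaluate`, `permtest`, and `compare` subcommands.

## Worked example

Simulate a session under the default study conditions (scaled to a
24-channel montage so the example runs in about a minute), preprocess it, and
compare the super-kernel SVC against a random-forest baseline:

```r
library(riemnirs)

design   <- make_design(seed = 3)                       # 8 tasks, 4 runs, 96 trials
profiles <- task_profiles(n_tasks = 8, n_channels = 24, seed = 3)
session  <- simulate_session(design, profiles,
                             sim_config(n_channels = 24, seed = 3))

report <- run_pipeline(models = c("SK-SVC", "RF", "LDA"),
                       session = session,
                       cv = cv_spec(k = 5, repeats = 1, seed = 1),
                       seed = 1)
report
#> # A tibble: 3 x 6
#>   model  type        mean_accuracy sd_accuracy ci_low ci_high
#>   <chr>  <chr>               <dbl>       <dbl>  <dbl>   <dbl>
#> 1 SK-SVC riemannian          0.698      0.139   0.593   0.804
#> 2 RF     traditional         0.262      0.131   0.174   0.368
#> 3 LDA    traditional         0.198      0.0460  0.164   0.232

compare_models(report)
#> # A tibble: 2 x 7
#>   baseline baseline_accuracy riemannian_model riemannian_accuracy   ris     t        p
#>   <chr>                <dbl> <chr>                          <dbl> <dbl> <dbl>    <dbl>
#> 1 RF                   0.262 SK-SVC                         0.698 0.592  4.01 0.0160
#> 2 LDA                  0.198 SK-SVC                         0.698 0.624  9.27 0.000753
```

The eight-choice task has a theoretical chance level of 12.5%; the
covariance-based model recovers the co-activation structure the generator
plants (mean accuracy 0.70 here), while the baselines see mostly the weak
evoked mean responses. `ris` is the improvement normalized by the headroom
to perfect accuracy — 0.59 means the super-kernel model closes 59% of the
gap between the random-forest baseline and perfect classification.
`autoplot(report)` draws the per-model accuracy distributions and
`plot_confusion(report)` the best model's confusion matrix.

Chance-level sanity check with label permutations:

```r
spec  <- model_spec("SK-SVC")
po    <- preprocess_recording(session$hbo)
pr    <- preprocess_recording(session$hbr)
feats <- build_features(po$epochs, pr$epochs, spec)
pc    <- permutation_chance(spec, feats, po$labels,
                            cv_spec(k = 5, repeats = 1, seed = 1),
                            n_perm = 19, seed = 1)
mean(pc$null)   # 0.1266 — near 0.125, the eight-choice chance level
pc$p_value      # 0.05 — the smallest value the add-one estimator allows at n_perm = 19
```

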