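test_that("stratified folds balance classes and are reproducible", {
  y96 <- rep(sprintf("t%d", 1:8), each = 12)
  folds <- stratified_folds(y96, cv_spec(k = 5, repeats = 3, seed = 2))
  expect_length(folds, 3)
  for (f in folds) {
    sizes <- as.vector(table(f))
    expect_true(all(sizes %in% c(19, 20)))  # 96 = 5*19 + 1
    per_class <- table(y96, f)
    expect_true(all(per_class %in% c(2, 3)))
  }
  # two classes of ten, five folds: exactly 2 + 2 per fold
  y20 <- rep(c("a", "b"), each = 10)
  f20 <- stratified_folds(y20, cv_spec(k = 5, repeats = 1, seed = 1))[[1]]
  expect_true(all(table(y20, f20) == 2))
  # determinism and reshuffling
  s1 <- stratified_folds(y96, cv_spec(k = 5, repeats = 2, seed = 9))
  s2 <- stratified_folds(y96, cv_spec(k = 5, repeats = 2, seed = 9))
  expect_identical(s1, s2)
  expect_false(identical(s1[[1]], s1[[2]]))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 12)),
                                cv_spec(k = 5, repeats = 1)), "smaller than k")
})

test_that("cross_validate returns k x repeats accuracies and a coherent
          confusion matrix", {
  set.seed(3)
  X <- matrix(rnorm(40 * 4), 40)
  # leaked label feature (jittered: exactly constant within class would be
  # rejected by LDA)
  X[, 1] <- ifelse(rep(c(TRUE, FALSE), 20), 3, -3) + rnorm(40, sd = 0.1)
  y <- rep(c("a", "b"), 20)
  spec <- model_spec("LDA")
  res <- cross_validate(spec, X, y, cv_spec(k = 5, repeats = 5, seed = 1))
  expect_length(res$accuracies, 25)
  expect_true(all(res$accuracies == 1))
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion),
               mean(res$accuracies))
  expect_equal(unname(rowSums(res$confusion)), rep(20 * 5, 2))
})

test_that("permutation p-values follow the add-one estimator", {
  set.seed(4)
  X <- matrix(rnorm(40 * 4), 40)
  X[, 1] <- rep(c(5, -5), 20) + rnorm(40, sd = 0.1)
  y <- rep(c("a", "b"), 20)
  spec <- model_spec("LDA")
  cv <- cv_spec(k = 5, repeats = 1, seed = 1)
  pc <- permutation_chance(spec, X, y, cv, n_perm = 19, seed = 1)
  # perfectly decodable: observed beats every shuffled null
  expect_equal(pc$p_value, 1 / 20)
  expect_equal(pc$observed, 1)
  expect_length(pc$null, 19)
  expect_error(permutation_chance(spec, X, y, cv, n_perm = 0), "n_perm")
})

test_that("permutation null is uniform when features are uninformative", {
  set.seed(5)
  X <- matrix(rnorm(30 * 3), 30)
  y <- rep(c("a", "b"), 15)
  spec <- model_spec("LDA")
  cv <- cv_spec(k = 3, repeats = 1, seed = 1)
  ps <- vapply(1:30, function(i) {
    permutation_chance(spec, X, sample(y), cv, n_perm = 19, seed = i)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("bootstrap CI behaves at its edges and matches the CLT", {
  expect_equal(bootstrap_mean_ci(rep(0.7, 10), seed = 1),
               tibble::tibble(mean = 0.7, ci_low = 0.7, ci_high = 0.7))
  set.seed(6)
  v <- rnorm(1000, mean = 2, sd = 0.5)
  bs <- bootstrap_mean_ci(v, n_boot = 1000, seed = 2)
  expect_lte(bs$ci_low, bs$mean)
  expect_lte(bs$mean, bs$ci_high)
  width <- bs$ci_high - bs$ci_low
  expect_lt(abs(width - 2 * 1.96 * sd(v) / sqrt(1000)) / width, 0.15)
  expect_identical(bootstrap_mean_ci(v, seed = 3),
                   bootstrap_mean_ci(v, seed = 3))
  expect_error(bootstrap_mean_ci(0.5), ">= 2")
})

test_that("paired t-test matches the textbook formula", {
  a <- c(1.0, 1.1, 0.9, 1.0)
  b <- c(0.8, 0.7, 0.85, 0.9)
  d <- a - b
  tt <- paired_t(a, b)
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(tt$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(tt$df, 3)
  rev_tt <- paired_t(b, a)
  expect_equal(rev_tt$t, -tt$t)
  expect_equal(rev_tt$p, tt$p)
  expect_error(paired_t(a, a), "zero-variance")
  expect_error(paired_t(a, b[1:3]), "equal length")
})

test_that("relative improvement normalizes by headroom", {
  expect_equal(relative_improvement(0.5, 1.0), 1.0)
  expect_equal(relative_improvement(0.3, 0.3), 0)
  expect_equal(relative_improvement(0.42, 0.62), 0.2 / 0.58)
  expect_lt(relative_improvement(0.6, 0.5), 0)
  expect_error(relative_improvement(1, 1), "\\[0, 1\\)")
})

test_that("1-D Wasserstein matches closed forms and the LP oracle", {
  # identical distributions
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  # point masses at a and b move all mass the distance |a - b|
  expect_equal(wasserstein_1d(0.2, 0.9), 0.7)
  # small discrete cases against the brute-force transport LP
  set.seed(7)
  for (i in 1:10) {
    x <- sort(runif(sample(2:5, 1)))
    y <- sort(runif(sample(2:5, 1)))
    wx <- runif(length(x)); wx <- wx / sum(wx)
    wy <- runif(length(y)); wy <- wy / sum(wy)
    expect_equal(wasserstein_1d(x, y, wx, wy), lp_wasserstein(x, y, wx, wy),
                 tolerance = 1e-10)
  }
})

test_that("the chromophore comparison is zero for identical inputs and
          positive under complementary structure", {
  sm <- small_session()
  # thin to 6 trials per task for speed (trials alternate within runs, so
  # subsetting must go by label, not by position)
  idx <- sort(unlist(lapply(split(seq_along(sm$labels), sm$labels), head, 6)))
  w0 <- wasserstein_compare(sm$hbo$epochs[idx], sm$hbo$epochs[idx],
                            sm$labels[idx], alpha = 0.1)
  expect_equal(w0$w, 0)
  expect_length(w0$dist_hbo, choose(8, 2))
  w1 <- wasserstein_compare(sm$hbo$epochs[idx], sm$hbr$epochs[idx],
                            sm$labels[idx], alpha = 0.1)
  expect_gt(w1$w, 0)
  expect_error(wasserstein_compare(sm$hbo$epochs[1:5], sm$hbr$epochs[1:5],
                                   rep("one", 5)), "2 tasks")
  gt <- wasserstein_group_test(c(0.01, 0.02, 0.03, 0.02))
  expect_gt(gt$t, 0)
})

test_that("an eight-task dataset defines exactly 28 binary problems", {
  bp <- binary_problems(rep(sprintf("t%d", 1:8), each = 12))
  expect_equal(nrow(bp), 28)
  expect_equal(nrow(unique(bp)), 28)
})
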