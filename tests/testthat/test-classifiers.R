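test_that("traditional features match hand computations", {
  x <- rbind(c(1, -1, 1, -1))
  f <- extract_traditional_features(x, x)
  expect_equal(unname(f["hbo_ch01_zero_crossings"]), 3)
  expect_equal(unname(f["hbo_ch01_mean"]), 0)
  expect_equal(unname(f["hbo_ch01_peak"]), 1)
  expect_length(f, 12)
  # constant channel: variance 0, zero crossings 0, moments flagged to 0
  expect_warning(fc <- extract_traditional_features(rbind(c(2, 2, 2, 2)),
                                                    rbind(c(1, 2, 1, 2))),
                 "constant channel")
  expect_equal(unname(fc["hbo_ch01_mean"]), 2)
  expect_equal(unname(fc["hbo_ch01_variance"]), 0)
  expect_equal(unname(fc["hbo_ch01_zero_crossings"]), 0)
  expect_equal(unname(fc["hbo_ch01_skew"]), 0)
  expect_equal(unname(fc["hbo_ch01_kurtosis"]), 0)
  # HbO block precedes HbR block
  expect_equal(unname(fc["hbr_ch01_zero_crossings"]), 0)  # 1,2,1,2 same sign
  # moments of a large standard-normal sample
  set.seed(1)
  z <- rbind(rnorm(1e5))
  fz <- extract_traditional_features(z, z)
  expect_lt(abs(fz[["hbo_ch01_skew"]]), 0.05)
  expect_lt(abs(fz[["hbo_ch01_kurtosis"]] - 3), 0.05)
})

test_that("model registry exposes exactly the fourteen benchmarked variants", {
  reg <- model_registry()
  expect_equal(nrow(reg), 14)
  expect_setequal(reg$model[reg$type == "riemannian"],
                  c("SK-SVC", "SK-TLR", "BK-SVC", "BK-TLR", "BC-SVC",
                    "BC-TLR", "BCI-SVC", "BCI-TLR", "C-SVC", "C-TLR"))
  expect_setequal(reg$model[reg$type == "traditional"],
                  c("LDA", "LR", "SVC", "RF"))
  expect_error(model_spec("XX-SVC"), "unknown model")
  expect_error(model_spec("BK-SVC", list(kernel_hbo = "scm")),
               "kernel functions")
  # BC shares one shrinkage across blocks
  sp <- model_spec("BC-TLR", list(shrinkage_hbo = 0.2, shrinkage_hbr = 0.5))
  expect_equal(sp$config$shrinkage_hbr, 0.2)
})

test_that("tangent-space classifiers separate orthogonal-pattern classes", {
  tr <- separable_spd_set(10, seed = 1)
  te <- separable_spd_set(6, seed = 2)
  for (fitter in list(fit_tslr, fit_rsvc)) {
    fit <- fitter(tr$feats, tr$labels, C = 1)
    expect_equal(mean(predict(fit, tr$feats) == tr$labels), 1)
    expect_equal(mean(predict(fit, te$feats) == te$labels), 1)
  }
  expect_error(fit_tslr(tr$feats, rep("a", 20)), "2 classes")
  expect_error(fit_rsvc(tr$feats, rep("a", 20)), "2 classes")
})

test_that("shuffled labels bring held-out accuracy to the permutation band", {
  tr <- separable_spd_set(10, seed = 3)
  spec <- model_spec("BC-TLR")
  set.seed(4)
  accs <- replicate(20, {
    y_perm <- sample(tr$labels)
    # glmnet warns about small per-class counts in these tiny folds
    mean(suppressWarnings(
      cross_validate(spec, tr$feats, y_perm,
                     cv_spec(k = 4, repeats = 1, seed = 1))$accuracies))
  })
  # two balanced classes: chance 0.5
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("the tangent Gram matrix is a PSD inner-product kernel", {
  tr <- separable_spd_set(6, seed = 5)
  M <- frechet_mean(tr$feats)
  Tv <- t(sapply(tr$feats, tangent_map, M = M))
  G <- tcrossprod(Tv)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  for (i in c(1, 5, 9)) {
    expect_equal(G[i, i], airm_distance(tr$feats[[i]], M)^2, tolerance = 1e-8)
  }
})

test_that("traditional baselines solve separable blobs and memorize", {
  set.seed(6)
  n <- 30
  X <- rbind(matrix(rnorm(n * 4, 0), n), matrix(rnorm(n * 4, 4), n))
  y <- rep(c("a", "b"), each = n)
  for (kind in c("LDA", "LR", "SVC", "RF")) {
    fit <- fit_traditional(X, y, kind, seed = 1)
    expect_equal(mean(predict(fit, X) == y), 1,
                 label = sprintf("training accuracy for %s", kind))
  }
  expect_error(fit_traditional(X, rep("a", 60), "LDA"), "2 classes")
  # pure-noise features with 8 balanced classes sit near chance 0.125
  set.seed(7)
  Xn <- matrix(rnorm(96 * 10), 96)
  yn <- rep(sprintf("t%d", 1:8), each = 12)
  spec <- model_spec("LDA")
  accs <- replicate(10, {
    mean(cross_validate(spec, Xn, sample(yn),
                        cv_spec(k = 5, repeats = 1, seed = 1))$accuracies)
  })
  expect_lt(abs(mean(accs) - 0.125), 0.05)
})

test_that("predictions are invariant to congruence transforms of all
          matrices", {
  tr <- separable_spd_set(8, c_ = 4, seed = 8)
  te <- separable_spd_set(4, c_ = 4, seed = 9)
  set.seed(10)
  G <- matrix(rnorm(16), 4, 4)
  cong <- function(feats) lapply(feats, function(S) G %*% S %*% t(G))
  for (fitter in list(fit_tslr, fit_rsvc)) {
    p1 <- fitter(tr$feats, tr$labels, C = 1)
    p2 <- fitter(cong(tr$feats), tr$labels, C = 1)
    expect_identical(predict(p1, te$feats), predict(p2, cong(te$feats)))
  }
})

test_that("permuting channel order consistently leaves block models
          unchanged", {
  sm <- small_session()
  idx <- 1:20
  spec <- model_spec("BC-SVC")
  f1 <- build_features(sm$hbo$epochs[idx], sm$hbr$epochs[idx], spec)
  perm <- c(4, 1, 3, 2, 5, 7, 6, 12, 9, 8, 11, 10)
  permute_epoch <- function(e) {
    e$values <- e$values[perm, , drop = FALSE]
    e
  }
  f2 <- build_features(lapply(sm$hbo$epochs[idx], permute_epoch),
                       lapply(sm$hbr$epochs[idx], permute_epoch), spec)
  y <- sm$labels[idx]
  cv <- cv_spec(k = 2, repeats = 1, seed = 3)
  a1 <- cross_validate(spec, f1, y, cv)$accuracies
  a2 <- cross_validate(spec, f2, y, cv)$accuracies
  expect_equal(a1, a2)
})

test_that("grid search evaluates every combination and keeps the audit
          trail", {
  sm <- small_session()
  idx <- 1:40
  y <- sm$labels[idx]
  eo <- sm$hbo$epochs[idx]
  er <- sm$hbr$epochs[idx]
  cv <- cv_spec(k = 2, repeats = 1, seed = 1)
  # glmnet warns about small per-class counts in these 2-fold fits
  one <- suppressWarnings(
    grid_search("BC-TLR", list(list(shrinkage_hbo = 0.1)), eo, er, y, cv))
  expect_equal(one$best_config$shrinkage_hbo, 0.1)
  expect_equal(nrow(one$results), 1)
  # a destructive configuration (full shrinkage wipes the signal) loses
  # against an informative one
  gs <- suppressWarnings(
    grid_search("SK-TLR",
                list(list(shrinkage_hbo = 1, shrinkage_hbr = 1),
                     list(shrinkage_hbo = 0.05, shrinkage_hbr = 0.05)),
                eo, er, y, cv))
  expect_equal(gs$best_config$shrinkage_hbo, 0.05)
  expect_equal(nrow(gs$results), 2)
  # exact ties resolve to the first grid entry
  tie <- suppressWarnings(
    grid_search("BC-TLR",
                list(list(shrinkage_hbo = 0.2), list(shrinkage_hbo = 0.2)),
                eo, er, y, cv))
  expect_equal(tie$results$mean_accuracy[1], tie$results$mean_accuracy[2])
  expect_identical(tie$best_config, list(shrinkage_hbo = 0.2))
  expect_error(grid_search("BC-TLR", list(), eo, er, y, cv), "nonempty")
})

test_that("tidy and glance methods describe fitted models", {
  tr <- separable_spd_set(6, seed = 11)
  ft <- suppressWarnings(fit_tslr(tr$feats, tr$labels))  # small-class glmnet note
  gl <- glance(ft)
  expect_equal(gl$tangent_dim, 10)  # 4x4 SPD -> 10 free parameters
  td <- tidy(ft)
  expect_true(all(c("class", "term", "estimate") %in% names(td)))
  fr <- fit_rsvc(tr$feats, tr$labels)
  expect_gt(glance(fr)$n_support, 0)
})
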