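#' Evaluation machinery
#'
#' Repeated stratified k-fold cross-validation, permutation-based chance
#' estimation, bootstrap confidence intervals, paired t-tests, the relative
#' improvement score, confusion matrices, and the Wasserstein comparison of
#' HbO/HbR co-activation structure.
#'
#' @name evaluation-stats
NULL

#' Cross-validation specification
#'
#' @param k number of folds (default 5).
#' @param repeats number of reshuffled repeats (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return object of class `riemnirs_cv_spec`.
#' @export
cv_spec <- function(k = 5, repeats = 5, seed = 1) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (repeats < 1) stop("`repeats` must be >= 1", call. = FALSE)
  structure(list(k = k, repeats = repeats, seed = seed),
            class = "riemnirs_cv_spec")
}

#' Stratified fold assignments
#'
#' Per repeat, every trial lands in exactly one test fold and per-fold
#' class counts differ from perfect proportion by at most one. Repeats
#' differ by reshuffling; assignments are deterministic given the seed.
#'
#' @param labels class labels, one per trial.
#' @param spec a [cv_spec()].
#' @return list of length `repeats`; each element an integer vector of fold
#'   ids (1..k) per trial.
#' @export
stratified_folds <- function(labels, spec = cv_spec()) {
  y <- factor(labels)
  counts <- table(y)
  if (any(counts < spec$k)) {
    small <- names(counts)[counts < spec$k]
    stop(sprintf("class(es) smaller than k = %d: %s", spec$k,
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  .with_seed(spec$seed, {
    lapply(seq_len(spec$repeats), function(r) {
      fold <- integer(length(y))
      # rotate the fold cycle across classes so fold sizes stay balanced
      # when class counts are not multiples of k
      offset <- 0L
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% spec$k) + 1L
        offset <- (offset + length(idx)) %% spec$k
      }
      fold
    })
  })
}

#' Repeated stratified cross-validation of one model
#'
#' The model (including any tangent-space reference point) is refitted on
#' every training fold; accuracy is the fraction correct on the held-out
#' fold.
#'
#' @param spec a [model_spec()].
#' @param features output of [build_features()] for this spec.
#' @param labels trial labels.
#' @param cv a [cv_spec()].
#' @return list with `accuracies` (length `k * repeats`), `predictions`
#'   (factor, last repeat), and `confusion` (confusion matrix pooled over
#'   all repeats).
#' @export
cross_validate <- function(spec, features, labels, cv = cv_spec()) {
  y <- factor(labels)
  folds <- stratified_folds(y, cv)
  is_list_feat <- is.list(features)
  n <- if (is_list_feat) length(features) else nrow(features)
  stopifnot(n == length(y))
  accs <- numeric(0)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(true = levels(y), predicted = levels(y)))
  preds <- factor(rep(NA_character_, n), levels = levels(y))
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    for (f in sort(unique(fold))) {
      tr <- which(fold != f)
      te <- which(fold == f)
      feat_tr <- if (is_list_feat) features[tr] else features[tr, , drop = FALSE]
      feat_te <- if (is_list_feat) features[te] else features[te, , drop = FALSE]
      fit <- fit_model(spec, feat_tr, y[tr])
      p <- predict(fit, feat_te)
      accs <- c(accs, mean(p == y[te]))
      conf <- conf + unclass(table(y[te], factor(p, levels = levels(y))))
      preds[te] <- p
    }
  }
  list(accuracies = accs, predictions = preds, confusion = conf)
}

#' Permutation-based chance-level estimation
#'
#' Shuffles the labels at the trial level (before fold construction),
#' re-runs the full cross-validation per permutation, and records the mean
#' accuracy; the p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param spec a [model_spec()].
#' @param features output of [build_features()] for this spec.
#' @param labels trial labels.
#' @param cv a [cv_spec()].
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @param observed optional precomputed observed mean accuracy; computed by
#'   one cross-validation run when missing.
#' @return list with `p_value`, `observed`, and `null` (length `n_perm`).
#' @export
permutation_chance <- function(spec, features, labels, cv = cv_spec(),
                               n_perm = 500, seed = 1, observed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  y <- factor(labels)
  if (is.null(observed)) {
    observed <- mean(cross_validate(spec, features, labels, cv)$accuracies)
  }
  null <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      y_perm <- sample(y)
      mean(cross_validate(spec, features, y_perm, cv)$accuracies)
    }, numeric(1))
  })
  list(p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       observed = observed, null = null)
}

#' Bootstrap mean and percentile confidence interval
#'
#' @param values numeric vector (e.g. cross-validation accuracies).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return tibble with `mean` (mean of bootstrap means), `ci_low`,
#'   `ci_high`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, level = 0.95, seed = 1) {
  if (length(values) < 2) stop("need >= 2 values to bootstrap", call. = FALSE)
  means <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(values, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  tibble::tibble(mean = mean(means), ci_low = q[1], ci_high = q[2])
}

#' Paired t-test with Cohen's d
#'
#' Classical paired t-test on the differences `a - b`, with effect size
#' `d = mean(diff) / sd(diff)`.
#'
#' @param a,b paired numeric vectors (e.g. per-participant accuracies).
#' @return tibble with `t`, `p`, `mean_diff`, `cohens_d`, `df`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 mean_diff = mean(d), cohens_d = mean(d) / stats::sd(d),
                 df = unname(tt$parameter))
}

#' Relative improvement score
#'
#' `RIS = (A_new - A_baseline) / (1 - A_baseline)`: the achieved gain
#' normalized by the headroom left to perfect accuracy, so improving on a
#' strong baseline counts more than the same absolute gain on a weak one.
#'
#' @param a_baseline baseline accuracy in `[0, 1)`.
#' @param a_new new model's accuracy in `[0, 1]`.
#' @return the score; 1 iff `a_new = 1`, 0 iff the accuracies are equal,
#'   negative when the new model is worse.
#' @export
relative_improvement <- function(a_baseline, a_new) {
  if (any(a_baseline < 0) || any(a_baseline >= 1)) {
    stop("`a_baseline` must be in [0, 1)", call. = FALSE)
  }
  if (any(a_new < 0) || any(a_new > 1)) {
    stop("`a_new` must be in [0, 1]", call. = FALSE)
  }
  (a_new - a_baseline) / (1 - a_baseline)
}

# ---- Wasserstein comparison -------------------------------------------------

#' 1-D Wasserstein distance between weighted discrete distributions
#'
#' Closed form via the integrated absolute difference of the two CDFs
#' (equivalently the L1 distance between quantile functions).
#'
#' @param x,y support points of the two distributions.
#' @param wx,wy nonnegative weights (default uniform); normalized to sum 1.
#' @return the W1 distance.
#' @export
wasserstein_1d <- function(x, y, wx = NULL, wy = NULL) {
  if (is.null(wx)) wx <- rep(1, length(x))
  if (is.null(wy)) wy <- rep(1, length(y))
  stopifnot(length(wx) == length(x), length(wy) == length(y),
            all(wx >= 0), all(wy >= 0), sum(wx) > 0, sum(wy) > 0)
  wx <- wx / sum(wx)
  wy <- wy / sum(wy)
  ox <- order(x); oy <- order(y)
  x <- x[ox]; wx <- wx[ox]
  y <- y[oy]; wy <- wy[oy]
  grid <- sort(unique(c(x, y)))
  if (length(grid) == 1) return(0)
  cdf <- function(s, w, g) {
    stats::stepfun(s, c(0, cumsum(w)))(g)
  }
  gm <- grid[-length(grid)]
  dx <- diff(grid)
  sum(abs(cdf(x, wx, gm) - cdf(y, wy, gm)) * dx)
}

#' Compare HbO and HbR co-activation structure via Wasserstein distance
#'
#' Per chromophore: Fréchet-mean kernel matrix per task, all pairwise AIRM
#' distances between task means (`choose(n_tasks, 2)` values), each
#' distance vector normalized to unit sum (a discrete probability
#' distribution over task pairs). The two normalized vectors are then
#' compared as empirical distributions on the real line with the 1-D
#' Wasserstein distance: a larger value means the two chromophores rank and
#' separate task pairs differently, i.e. carry different co-activation
#' information.
#'
#' @param epochs_hbo,epochs_hbr lists of epochs, matched by trial.
#' @param labels task labels, one per trial; >= 2 tasks.
#' @param estimator kernel estimator used per trial (default `"scm"`).
#' @param alpha shrinkage applied per trial matrix (default 0.01).
#' @param normalize `"sum"` (default) normalizes each distance vector to
#'   unit sum before the comparison; `"histogram"` instead compares
#'   histogram-binned distance distributions.
#' @param bins number of bins for the histogram reading.
#' @return list with `w` (the Wasserstein statistic), `dist_hbo`,
#'   `dist_hbr` (named pairwise distance vectors), and `task_means`.
#' @export
wasserstein_compare <- function(epochs_hbo, epochs_hbr, labels,
                                estimator = "scm", alpha = 0.01,
                                normalize = c("sum", "histogram"), bins = 10) {
  normalize <- match.arg(normalize)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need >= 2 tasks", call. = FALSE)
  task_mean <- function(epochs) {
    lapply(levels(y), function(cl) {
      Ks <- lapply(which(y == cl), function(i) {
        shrink(estimate_kernel(epochs[[i]], estimator = estimator), alpha)
      })
      frechet_mean(Ks)
    })
  }
  mo <- task_mean(epochs_hbo)
  mr <- task_mean(epochs_hbr)
  pairs <- utils::combn(nlevels(y), 2)
  pair_names <- apply(pairs, 2, function(p) {
    paste(levels(y)[p], collapse = "|")
  })
  pdist <- function(ms) {
    stats::setNames(apply(pairs, 2, function(p) {
      airm_distance(ms[[p[1]]], ms[[p[2]]])
    }), pair_names)
  }
  do_ <- pdist(mo)
  dr_ <- pdist(mr)
  po <- do_ / sum(do_)
  pr <- dr_ / sum(dr_)
  w <- if (normalize == "sum") {
    wasserstein_1d(po, pr)
  } else {
    rng <- range(c(do_, dr_))
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    mids <- (brk[-1] + brk[-length(brk)]) / 2
    ho <- graphics::hist(do_, breaks = brk, plot = FALSE)$counts
    hr <- graphics::hist(dr_, breaks = brk, plot = FALSE)$counts
    wasserstein_1d(mids, mids, ho, hr)
  }
  list(w = w, dist_hbo = do_, dist_hbr = dr_,
       task_means = list(hbo = mo, hbr = mr))
}

#' Group-level test of the Wasserstein statistic
#'
#' One-sample t-test of per-participant Wasserstein statistics against
#' zero.
#'
#' @param w_values per-participant Wasserstein statistics.
#' @return tibble with `t`, `p`, `mean_w`, `df`.
#' @export
wasserstein_group_test <- function(w_values) {
  if (length(w_values) < 2) stop("need >= 2 participants", call. = FALSE)
  tt <- stats::t.test(w_values, mu = 0)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 mean_w = mean(w_values), df = unname(tt$parameter))
}

#' Enumerate the pairwise binary problems of a multi-task dataset
#'
#' @param labels task labels.
#' @return tibble with one row per unordered task pair (`task_a`,
#'   `task_b`): `choose(n_tasks, 2)` rows.
#' @export
binary_problems <- function(labels) {
  tasks <- levels(factor(labels))
  pairs <- utils::combn(tasks, 2)
  tibble::tibble(task_a = pairs[1, ], task_b = pairs[2, ])
}
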