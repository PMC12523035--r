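#' Riemannian and traditional classifiers
#'
#' Fourteen model variants: ten Riemannian ones crossing five feature
#' constructions (super kernel SK, block kernel BK, block covariance with
#' shared shrinkage BC, block covariance with individual shrinkage BCI, and
#' the full concatenated matrix C) with two classifiers (Riemannian support
#' vector classifier SVC on the tangent-space Gram matrix, and tangent-space
#' logistic regression TLR), plus four traditional baselines (LDA, LR, SVC,
#' RF) on per-channel summary features.
#'
#' @name classifiers
NULL

.moments_features <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)  # population variance
  peak <- max(abs(x))
  s <- sign(x)
  s <- s[s != 0]        # zeros skipped
  zc <- if (length(s) > 1) sum(diff(s) != 0) else 0L
  if (v == 0) {
    warning("constant channel: skew/kurtosis set to 0")
    sk <- 0
    ku <- 0
  } else {
    sd_ <- sqrt(v)
    sk <- mean((x - m)^3) / sd_^3
    ku <- mean((x - m)^4) / sd_^4  # Pearson kurtosis (3 for a Gaussian)
  }
  c(mean = m, variance = v, peak = peak, zero_crossings = zc,
    skew = sk, kurtosis = ku)
}

#' Traditional per-channel summary features for one trial
#'
#' Per channel and chromophore: mean, population variance, peak (maximum
#' absolute amplitude), zero crossings (strict sign changes, zeros
#' skipped), skew, and Pearson kurtosis. The HbO block precedes the HbR
#' block; total length `2 * c * 6`.
#'
#' @param epoch_hbo,epoch_hbr epochs (or `c x t` matrices) with equal
#'   channel counts.
#' @return named numeric vector of length `2 * c * 6`.
#' @export
extract_traditional_features <- function(epoch_hbo, epoch_hbr) {
  Vo <- .epoch_values(epoch_hbo)
  Vr <- .epoch_values(epoch_hbr)
  if (nrow(Vo) != nrow(Vr)) {
    stop("HbO and HbR must have the same channel count", call. = FALSE)
  }
  fo <- as.numeric(t(apply(Vo, 1, .moments_features)))
  fr <- as.numeric(t(apply(Vr, 1, .moments_features)))
  feat_names <- c("mean", "variance", "peak", "zero_crossings", "skew", "kurtosis")
  nm <- function(chrom, c_) {
    as.vector(t(outer(sprintf("%s_ch%02d", chrom, seq_len(c_)), feat_names, paste, sep = "_")))
  }
  stats::setNames(c(fo, fr), c(nm("hbo", nrow(Vo)), nm("hbr", nrow(Vr))))
}

# ---- model registry ---------------------------------------------------------

#' The fourteen benchmarked model variants
#'
#' @return tibble with columns `model`, `type`, `feature`, `classifier`.
#' @export
model_registry <- function() {
  riem <- expand.grid(feature = c("SK", "BK", "BC", "BCI", "C"),
                      classifier = c("SVC", "TLR"), stringsAsFactors = FALSE)
  tibble::tibble(
    model = c(paste(riem$feature, riem$classifier, sep = "-"),
              "LDA", "LR", "SVC", "RF"),
    type = c(rep("riemannian", nrow(riem)), rep("traditional", 4)),
    feature = c(riem$feature, rep("traditional", 4)),
    classifier = c(riem$classifier, "LDA", "LR", "SVC", "RF")
  )
}

# Kernel-only estimator names allowed in the BK variant.
.kernel_only <- c("poly", "rbf", "laplacian", "cosine")

#' Specify one of the registered models
#'
#' @param model a name from [model_registry()].
#' @param config named list of model parameters. Riemannian variants accept
#'   `kernel_hbo`, `kernel_hbr` (SK: any registered estimator; BK: kernel
#'   functions only; BC/BCI: fixed to the sample covariance), `shrinkage_hbo`,
#'   `shrinkage_hbr` (BC forces them equal), `estimator` and `alpha` for the
#'   full variant C, and `C` (classifier regularization). Traditional models
#'   accept `C` (LR, SVC), `ntree` (RF).
#' @return object of class `riemnirs_model_spec`.
#' @export
model_spec <- function(model, config = list()) {
  reg <- model_registry()
  row <- reg[reg$model == model, ]
  if (nrow(row) == 0) {
    stop(sprintf("unknown model '%s'; see model_registry()", model), call. = FALSE)
  }
  defaults <- list(C = 1)
  if (row$feature %in% c("SK", "BK")) {
    defaults <- c(defaults, list(
      kernel_hbo = if (row$feature == "BK") "rbf" else "scm",
      kernel_hbr = if (row$feature == "BK") "rbf" else "scm",
      shrinkage_hbo = 0.01, shrinkage_hbr = 0.01))
  } else if (row$feature %in% c("BC", "BCI")) {
    defaults <- c(defaults, list(shrinkage_hbo = 0.01, shrinkage_hbr = 0.01))
  } else if (row$feature == "C") {
    defaults <- c(defaults, list(estimator = "scm", alpha = 0.01))
  } else if (row$classifier == "RF") {
    defaults <- c(defaults, list(ntree = 200, seed = 1))
  }
  config <- utils::modifyList(defaults, config)
  if (row$feature == "BK") {
    for (k in c("kernel_hbo", "kernel_hbr")) {
      if (!config[[k]] %in% .kernel_only) {
        stop(sprintf("BK models require kernel functions (%s); got '%s'",
                     paste(.kernel_only, collapse = ", "), config[[k]]),
             call. = FALSE)
      }
    }
  }
  if (row$feature == "BC") config$shrinkage_hbr <- config$shrinkage_hbo
  structure(list(model = model, type = row$type, feature = row$feature,
                 classifier = row$classifier, config = config),
            class = "riemnirs_model_spec")
}

#' Build per-trial features for a model variant
#'
#' Riemannian variants return a list of SPD matrices (one per trial);
#' traditional variants return an `n x p` feature matrix.
#'
#' @param epochs_hbo,epochs_hbr lists of epochs, matched by trial.
#' @param spec a [model_spec()].
#' @return list of SPD matrices or a numeric matrix.
#' @export
build_features <- function(epochs_hbo, epochs_hbr, spec) {
  stopifnot(inherits(spec, "riemnirs_model_spec"),
            length(epochs_hbo) == length(epochs_hbr))
  cfg <- spec$config
  n <- length(epochs_hbo)
  if (spec$feature == "traditional") {
    return(t(vapply(seq_len(n), function(i) {
      extract_traditional_features(epochs_hbo[[i]], epochs_hbr[[i]])
    }, numeric(12 * nrow(.epoch_values(epochs_hbo[[1]]))))))
  }
  if (spec$feature == "C") {
    return(lapply(seq_len(n), function(i) {
      build_full_kernel(epochs_hbo[[i]], epochs_hbr[[i]],
                        estimator = cfg$estimator, alpha = cfg$alpha)
    }))
  }
  bc <- if (spec$feature %in% c("BC", "BCI")) {
    block_kernel_config("scm", "scm", cfg$shrinkage_hbo, cfg$shrinkage_hbr)
  } else {
    block_kernel_config(cfg$kernel_hbo, cfg$kernel_hbr,
                        cfg$shrinkage_hbo, cfg$shrinkage_hbr)
  }
  lapply(seq_len(n), function(i) {
    build_block_kernel(epochs_hbo[[i]], epochs_hbr[[i]], bc)
  })
}

# ---- Riemannian classifiers -------------------------------------------------

# Shared block structure of a feature set, or NULL. Block-diagonal SPD
# matrices form a product manifold, so Fréchet means and tangent maps
# factor exactly into per-block computations (much cheaper, and the
# tangent dimension drops to the block manifold dimension).
.common_blocks <- function(feats) {
  bs <- lapply(feats, attr, "block_sizes")
  if (any(vapply(bs, is.null, logical(1)))) return(NULL)
  if (length(unique(bs)) != 1) return(NULL)
  bs[[1]]
}

.block_index <- function(block_sizes) {
  ends <- cumsum(block_sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  Map(seq, starts, ends)
}

# Tangent references tolerate a looser mean (1e-6): classifier decisions
# are insensitive at that scale and the fixed point slows near solution.
.frechet_feats <- function(feats, tol = 1e-6, max_iter = 120) {
  bs <- .common_blocks(feats)
  if (is.null(bs)) return(frechet_mean(feats, tol = tol, max_iter = max_iter))
  idx <- .block_index(bs)
  n <- sum(bs)
  M <- matrix(0, n, n)
  for (ib in idx) {
    M[ib, ib] <- frechet_mean(lapply(feats, function(S) S[ib, ib, drop = FALSE]),
                              tol = tol, max_iter = max_iter)
  }
  attr(M, "block_sizes") <- bs
  M
}

.tangent_matrix <- function(feats, reference) {
  bs <- attr(reference, "block_sizes")
  if (is.null(bs)) {
    return(t(vapply(feats, tangent_map,
                    numeric(nrow(reference) * (nrow(reference) + 1) / 2),
                    M = reference)))
  }
  idx <- .block_index(bs)
  do.call(cbind, lapply(idx, function(ib) {
    Mb <- reference[ib, ib, drop = FALSE]
    t(vapply(feats, function(S) tangent_map(S[ib, ib, drop = FALSE], Mb),
             numeric(length(ib) * (length(ib) + 1) / 2)))
  }))
}

# Ridge (multinomial) logistic fit at one target lambda. glmnet's
# multinomial path can fail when handed a single lambda, so fit a short
# decreasing path and predict at the target.
.ridge_logistic <- function(X, y, C) {
  lam <- 1 / (nrow(X) * C)
  fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
  fit <- glmnet::glmnet(X, y, family = fam, alpha = 0,
                        lambda = c(100 * lam, 10 * lam, lam),
                        standardize = FALSE)
  list(fit = fit, lambda = lam)
}

.check_labels <- function(labels) {
  y <- factor(labels)
  if (nlevels(y) < 2) {
    stop("need at least 2 classes to fit a classifier", call. = FALSE)
  }
  y
}

#' Tangent-space logistic regression
#'
#' Maps all training matrices to the tangent space at their Fréchet mean
#' and fits an L2-penalized (multinomial) logistic regression on the
#' tangent vectors; `C` follows the usual inverse-regularization convention
#' (`lambda = 1 / (n * C)`).
#'
#' @param feats list of SPD feature matrices.
#' @param labels class labels, one per matrix.
#' @param C inverse regularization strength.
#' @return object of class `riemnirs_tslr`.
#' @export
fit_tslr <- function(feats, labels, C = 1) {
  y <- .check_labels(labels)
  M <- .frechet_feats(feats)
  Tv <- .tangent_matrix(feats, M)
  rl <- .ridge_logistic(Tv, y, C)
  structure(list(reference = M, fit = rl$fit, lambda = rl$lambda,
                 classes = levels(y), C = C),
            class = "riemnirs_tslr")
}

#' @export
predict.riemnirs_tslr <- function(object, newdata, ...) {
  Tv <- .tangent_matrix(newdata, object$reference)
  cls <- as.character(predict(object$fit, newx = Tv, type = "class",
                              s = object$lambda))
  factor(cls, levels = object$classes)
}

#' Riemannian support vector classifier
#'
#' SVC under the tangent-space kernel
#' `G(A, B) = <tangent_map(A, M), tangent_map(B, M)>` with `M` the training
#' Fréchet mean — realized as a linear SVM on the tangent vectors, whose
#' internal kernel is exactly this Gram matrix; one-vs-rest for more than
#' two classes. Test matrices are mapped at the training reference.
#'
#' @param feats list of SPD feature matrices.
#' @param labels class labels.
#' @param C SVC cost parameter.
#' @return object of class `riemnirs_rsvc`.
#' @export
fit_rsvc <- function(feats, labels, C = 1) {
  y <- .check_labels(labels)
  M <- .frechet_feats(feats)
  Tv <- .tangent_matrix(feats, M)
  classes <- levels(y)
  fits <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(Tv, yy, kernel = "linear", cost = C, scale = FALSE)
    # orient the decision value so the target class scores high
    d_train <- attr(predict(m, Tv, decision.values = TRUE),
                    "decision.values")[, 1]
    sgn <- if (mean(d_train[y == cl]) >= mean(d_train[y != cl])) 1 else -1
    list(m = m, sgn = sgn)
  })
  structure(list(reference = M, fits = fits, classes = classes, C = C),
            class = "riemnirs_rsvc")
}

#' @export
predict.riemnirs_rsvc <- function(object, newdata, ...) {
  Tv <- .tangent_matrix(newdata, object$reference)
  D <- vapply(object$fits, function(f) {
    d <- attr(predict(f$m, Tv, decision.values = TRUE),
              "decision.values")[, 1]
    f$sgn * as.numeric(d)
  }, numeric(nrow(Tv)))
  D <- matrix(D, nrow = nrow(Tv))
  factor(object$classes[max.col(D, ties.method = "first")],
         levels = object$classes)
}

# ---- traditional classifiers ------------------------------------------------

#' Traditional baselines on summary-feature vectors
#'
#' Fits LDA, L2 logistic regression, RBF-kernel SVC, or a random forest on
#' features standardized with training-fold statistics (zero-variance
#' columns dropped).
#'
#' @param X `n x p` feature matrix.
#' @param labels class labels.
#' @param kind one of `"LDA"`, `"LR"`, `"SVC"`, `"RF"`.
#' @param C inverse regularization / cost for LR and SVC.
#' @param ntree number of random-forest trees.
#' @param seed seed for the random forest.
#' @return object of class `riemnirs_traditional`.
#' @export
fit_traditional <- function(X, labels, kind = c("LDA", "LR", "SVC", "RF"),
                            C = 1, ntree = 200, seed = 1) {
  kind <- match.arg(kind)
  y <- .check_labels(labels)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- which(scl > 0)
  if (length(keep) == 0) stop("all features are constant", call. = FALSE)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  fit <- switch(kind,
    LDA = suppressWarnings(MASS::lda(Xs, grouping = y)),
    LR = .ridge_logistic(Xs, y, C),
    SVC = e1071::svm(Xs, y, kernel = "radial", cost = C, scale = FALSE),
    RF = .with_seed(seed, randomForest::randomForest(Xs, y, ntree = ntree))
  )
  structure(list(kind = kind, fit = fit, center = ctr, scale = scl,
                 keep = keep, classes = levels(y)),
            class = "riemnirs_traditional")
}

#' @export
predict.riemnirs_traditional <- function(object, newdata, ...) {
  Xs <- sweep(sweep(newdata[, object$keep, drop = FALSE], 2,
                    object$center[object$keep]), 2,
              object$scale[object$keep], "/")
  cls <- switch(object$kind,
    LDA = as.character(predict(object$fit, Xs)$class),
    LR = as.character(predict(object$fit$fit, newx = Xs, type = "class",
                              s = object$fit$lambda)),
    SVC = as.character(predict(object$fit, Xs)),
    RF = as.character(predict(object$fit, Xs))
  )
  factor(cls, levels = object$classes)
}

#' Fit any registered model on prebuilt features
#'
#' @param spec a [model_spec()].
#' @param features output of [build_features()] for this spec.
#' @param labels class labels.
#' @return a fitted model object with a `predict()` method.
#' @export
fit_model <- function(spec, features, labels) {
  stopifnot(inherits(spec, "riemnirs_model_spec"))
  cfg <- spec$config
  switch(spec$classifier,
    TLR = fit_tslr(features, labels, C = cfg$C),
    SVC = if (spec$type == "riemannian") {
      fit_rsvc(features, labels, C = cfg$C)
    } else {
      fit_traditional(features, labels, "SVC", C = cfg$C)
    },
    LDA = fit_traditional(features, labels, "LDA"),
    LR = fit_traditional(features, labels, "LR", C = cfg$C),
    RF = fit_traditional(features, labels, "RF", ntree = cfg$ntree,
                         seed = cfg$seed)
  )
}

# ---- grid search ------------------------------------------------------------

#' Exhaustive grid search over model configurations
#'
#' Evaluates every configuration in `grid` by stratified cross-validation
#' (features rebuilt per configuration, models refitted per fold) and
#' returns the best configuration by mean accuracy; ties are broken by
#' first-in-grid order. The full result table is retained for audit.
#'
#' @param model a name from [model_registry()].
#' @param grid list of configuration lists (each as `config` in
#'   [model_spec()]).
#' @param epochs_hbo,epochs_hbr lists of epochs.
#' @param labels trial labels.
#' @param cv a [cv_spec()].
#' @return list with `best_config`, `best_spec`, `best_accuracy`, and
#'   `results` (tibble: one row per configuration).
#' @export
grid_search <- function(model, grid, epochs_hbo, epochs_hbr, labels,
                        cv = cv_spec()) {
  if (length(grid) == 0) stop("`grid` must be nonempty", call. = FALSE)
  rows <- vector("list", length(grid))
  accs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    spec <- model_spec(model, grid[[i]])
    feats <- build_features(epochs_hbo, epochs_hbr, spec)
    cvres <- cross_validate(spec, feats, labels, cv)
    accs[i] <- mean(cvres$accuracies)
    rows[[i]] <- tibble::tibble(
      config_id = i,
      config = list(grid[[i]]),
      mean_accuracy = accs[i],
      sd_accuracy = stats::sd(cvres$accuracies)
    )
  }
  best <- which.max(accs)  # which.max takes the first maximum: tie rule
  list(best_config = grid[[best]],
       best_spec = model_spec(model, grid[[best]]),
       best_accuracy = accs[best],
       results = dplyr::bind_rows(rows))
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method glance riemnirs_tslr
#' @export
glance.riemnirs_tslr <- function(x, ...) {
  B <- x$fit$beta
  tibble::tibble(classifier = "TLR", n_classes = length(x$classes),
                 tangent_dim = nrow(if (is.list(B)) B[[1]] else B),
                 C = x$C)
}

#' @method glance riemnirs_rsvc
#' @export
glance.riemnirs_rsvc <- function(x, ...) {
  tibble::tibble(classifier = "RSVC", n_classes = length(x$classes),
                 n_support = sum(vapply(x$fits, function(f)
                   f$m$tot.nSV, numeric(1))),
                 C = x$C)
}

#' @method tidy riemnirs_tslr
#' @export
tidy.riemnirs_tslr <- function(x, ...) {
  B <- x$fit$beta
  if (!is.list(B)) B <- stats::setNames(list(B), x$classes[2])
  purrr::map_dfr(names(B), function(cl) {
    b <- as.numeric(B[[cl]][, ncol(B[[cl]])])  # coefficients at the target lambda
    tibble::tibble(class = cl, term = seq_along(b), estimate = b)
  })
}
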