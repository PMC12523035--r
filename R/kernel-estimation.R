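#' Channel kernel and covariance estimation
#'
#' Every classifier feature in this package is a channel-by-channel kernel
#' or covariance matrix estimated from one trial's multichannel time series.
#' The registry exposes twelve estimators under their conventional short
#' names; each maps a `c x t` matrix (c channels, t samples) to a `c x c`
#' symmetric matrix. Robust and shrunk covariance estimators act on
#' channel-centered data; the nonlinear pairwise kernels (poly, rbf,
#' laplacian, cosine) act on the rows as given, which after whole-recording
#' z-scoring are already near zero mean.
#'
#' @name kernel-estimation
NULL

#' Construct a multichannel epoch
#'
#' One trial's `c x t` concentration matrix for one chromophore.
#'
#' @param values numeric `c x t` matrix (channels by samples).
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `riemnirs_epoch`.
#' @export
multichannel_epoch <- function(values, chromophore = c("HbO", "HbR"),
                               sample_rate = 3.47) {
  chromophore <- match.arg(chromophore)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("epoch needs >= 1 channel and >= 2 samples", call. = FALSE)
  }
  if (anyNA(values)) stop("epoch contains missing values", call. = FALSE)
  structure(list(values = values, chromophore = chromophore,
                 sample_rate = sample_rate),
            class = "riemnirs_epoch")
}

.epoch_values <- function(X) {
  if (inherits(X, "riemnirs_epoch")) X$values else X
}

# ---- estimator registry -----------------------------------------------------

.center_rows <- function(X) X - rowMeans(X)

.est_scm <- function(X, ...) {
  Xc <- .center_rows(X)
  tcrossprod(Xc) / ncol(X)
}

.est_corr <- function(X, ...) {
  C <- stats::cor(t(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

# Ledoit-Wolf shrinkage toward the scaled identity mu*I; analytic intensity.
.est_lwf <- function(X, ...) {
  Xc <- .center_rows(X)
  n <- ncol(X)
  p <- nrow(X)
  S <- tcrossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  b_bar <- 0
  for (k in seq_len(n)) {
    xk <- Xc[, k]
    b_bar <- b_bar + sum((tcrossprod(xk) - S)^2)
  }
  b_bar <- b_bar / (n^2 * p)
  b2 <- min(b_bar, d2)
  alpha <- if (d2 > 0) b2 / d2 else 0
  out <- (1 - alpha) * S + alpha * diag(mu, p)
  attr(out, "intensity") <- alpha
  out
}

# Oracle-approximating shrinkage toward mu*I (Chen et al. intensity).
.est_oas <- function(X, ...) {
  Xc <- .center_rows(X)
  n <- ncol(X)
  p <- nrow(X)
  S <- tcrossprod(Xc) / n
  mu <- sum(diag(S)) / p
  tr_s2 <- sum(S^2)
  tr_s <- sum(diag(S))
  num <- (1 - 2 / p) * tr_s2 + tr_s^2
  den <- (n + 1 - 2 / p) * (tr_s2 - tr_s^2 / p)
  alpha <- if (den > 0) min(num / den, 1) else 1
  out <- (1 - alpha) * S + alpha * diag(mu, p)
  attr(out, "intensity") <- alpha
  out
}

# Schaefer-Strimmer analytic intensity toward mu*I: lambda* =
# sum Var-hat(s_ij) / sum (s_ij - target_ij)^2, with entrywise variances
# estimated from the per-sample cross products.
.est_sch <- function(X, ...) {
  Xc <- .center_rows(X)
  n <- ncol(X)
  p <- nrow(X)
  S <- tcrossprod(Xc) / n
  mu <- sum(diag(S)) / p
  var_sum <- 0
  for (i in seq_len(p)) {
    Wi <- Xc * rep(Xc[i, ], each = p)  # w_k(i, j) across columns
    wbar <- rowMeans(Wi)
    var_sum <- var_sum + n / (n - 1)^3 * sum((Wi - wbar)^2)
  }
  mis_sum <- sum((S - diag(mu, p))^2)
  alpha <- if (mis_sum > 0) max(0, min(1, var_sum / mis_sum)) else 1
  out <- (1 - alpha) * S + alpha * diag(mu, p)
  attr(out, "intensity") <- alpha
  out
}

# Inverse with a tiny trace-scaled ridge so the M-estimator fixed points
# stay defined on rank-deficient iterates (c > t is not guarded; shrinkage
# handles rank deficiency downstream).
.ridge_solve <- function(S) {
  p <- nrow(S)
  solve(S + diag(1e-9 * max(sum(diag(S)) / p, .Machine$double.eps), p))
}

# Huber M-estimator of scatter: fixed-point iteration where samples with
# squared Mahalanobis distance beyond the clean-fraction chi-square
# quantile are downweighted proportionally.
.est_hub <- function(X, clean_frac = 0.9, tol = 1e-6, max_iter = 100, ...) {
  Xc <- .center_rows(X)
  n <- ncol(X)
  p <- nrow(X)
  q <- stats::qchisq(clean_frac, df = p)
  S <- tcrossprod(Xc) / n
  for (it in seq_len(max_iter)) {
    Sinv <- .ridge_solve(S)
    d2 <- colSums(Xc * (Sinv %*% Xc))
    w <- ifelse(d2 <= q, 1, q / d2)
    Snew <- (Xc %*% (w * t(Xc))) / sum(w)
    Snew <- (Snew + t(Snew)) / 2
    delta <- sum((Snew - S)^2) / max(sum(S^2), .Machine$double.eps)
    S <- Snew
    if (sqrt(delta) < tol) break
  }
  S
}

# Tyler's distribution-free M-estimator, trace-normalized to c; invariant
# to per-sample rescaling of the data.
.est_tyl <- function(X, tol = 1e-6, max_iter = 100, ...) {
  Xc <- .center_rows(X)
  n <- ncol(X)
  p <- nrow(X)
  S <- diag(p)
  for (it in seq_len(max_iter)) {
    Sinv <- .ridge_solve(S)
    d2 <- colSums(Xc * (Sinv %*% Xc))
    d2 <- pmax(d2, 1e-24)
    Snew <- (p / n) * (Xc %*% (t(Xc) / d2))
    Snew <- (Snew + t(Snew)) / 2
    Snew <- Snew * (p / sum(diag(Snew)))
    delta <- sqrt(sum((Snew - S)^2) / max(sum(S^2), .Machine$double.eps))
    S <- Snew
    if (delta < tol) break
  }
  S
}

.est_poly <- function(X, gamma = NULL, degree = 3, coef0 = 1, ...) {
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  (gamma * tcrossprod(X) + coef0)^degree
}

.est_rbf <- function(X, gamma = NULL, ...) {
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

.est_laplacian <- function(X, gamma = NULL, ...) {
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  p <- nrow(X)
  D <- matrix(0, p, p)
  for (i in seq_len(p)) {
    D[i, ] <- colSums(abs(t(X) - X[i, ]))
  }
  exp(-gamma * (D + t(D)) / 2)
}

.est_cosine <- function(X, ...) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  G <- tcrossprod(X / nrm)
  G[G > 1] <- 1
  G[G < -1] <- -1
  G
}

.estimator_registry <- list(
  corr = .est_corr,
  cov = .est_scm,   # alias: both names denote the centered sample covariance
  scm = .est_scm,
  lwf = .est_lwf,
  oas = .est_oas,
  sch = .est_sch,
  hub = .est_hub,
  tyl = .est_tyl,
  poly = .est_poly,
  rbf = .est_rbf,
  laplacian = .est_laplacian,
  cosine = .est_cosine
)

#' Names of the registered kernel/covariance estimators
#' @return character vector of estimator names.
#' @export
kernel_estimators <- function() names(.estimator_registry)

# Estimators whose entry (i, j) depends only on channels i and j.
.pairwise_estimators <- c("corr", "cov", "scm", "poly", "rbf", "laplacian", "cosine")

#' Estimate a channel kernel/covariance matrix
#'
#' Applies a registered estimator to a multichannel epoch. Tiny negative
#' eigenvalues (above `-1e-10 * lambda_max`) are clipped to zero; anything
#' more negative raises, since it indicates a broken estimator rather than
#' rounding.
#'
#' @param X a `riemnirs_epoch` or a numeric `c x t` matrix.
#' @param estimator estimator name; see [kernel_estimators()].
#' @param ... estimator parameters (`gamma`, `degree`, `coef0`,
#'   `clean_frac`, `tol`, `max_iter` where applicable).
#' @return symmetric `c x c` matrix (positive semi-definite).
#' @export
estimate_kernel <- function(X, estimator = "scm", ...) {
  fn <- .estimator_registry[[estimator]]
  if (is.null(fn)) {
    stop(sprintf("unknown estimator '%s'; see kernel_estimators()", estimator),
         call. = FALSE)
  }
  V <- .epoch_values(X)
  if (!is.matrix(V) || ncol(V) < 2) {
    stop("`X` must have >= 2 time samples", call. = FALSE)
  }
  K <- fn(V, ...)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(e, 0)
  if (min(e) < -1e-10 * max(lmax, 1)) {
    stop(sprintf("estimator '%s' returned an indefinite matrix (lambda_min = %g)",
                 estimator, min(e)), call. = FALSE)
  }
  if (min(e) < 0) {
    ed <- eigen(K, symmetric = TRUE)
    K <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
    K <- (K + t(K)) / 2
  }
  K
}

#' Shrink a kernel matrix toward the scaled identity
#'
#' `(1 - alpha) * K + alpha * mu * I` with `mu = trace(K) / c`, the
#' regularization that guarantees positive-definiteness of each chromophore
#' block before assembly.
#'
#' @param K symmetric positive semi-definite matrix.
#' @param alpha shrinkage intensity in `[0, 1]`.
#' @return shrunk matrix; SPD whenever `alpha > 0` and `trace(K) > 0`.
#' @export
shrink <- function(K, alpha) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("`K` must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a scalar in [0, 1]", call. = FALSE)
  }
  tr <- sum(diag(K))
  if (tr < 0) stop("`K` has negative trace", call. = FALSE)
  mu <- tr / nrow(K)
  (1 - alpha) * K + alpha * diag(mu, nrow(K))
}

#' Per-chromophore kernel configuration for block features
#'
#' @param kernel_hbo,kernel_hbr estimator names for the HbO/HbR blocks.
#' @param shrinkage_hbo,shrinkage_hbr shrinkage intensities in `[0, 1]`.
#' @param params_hbo,params_hbr optional lists of estimator parameters.
#' @return object of class `riemnirs_block_config`.
#' @export
block_kernel_config <- function(kernel_hbo = "scm", kernel_hbr = "scm",
                                shrinkage_hbo = 0.01, shrinkage_hbr = 0.01,
                                params_hbo = list(), params_hbr = list()) {
  for (nm in c(kernel_hbo, kernel_hbr)) {
    if (!nm %in% kernel_estimators()) {
      stop(sprintf("unknown estimator '%s'; see kernel_estimators()", nm),
           call. = FALSE)
    }
  }
  for (a in c(shrinkage_hbo, shrinkage_hbr)) {
    if (a < 0 || a > 1) stop("shrinkage must be in [0, 1]", call. = FALSE)
  }
  structure(list(kernel_hbo = kernel_hbo, kernel_hbr = kernel_hbr,
                 shrinkage_hbo = shrinkage_hbo, shrinkage_hbr = shrinkage_hbr,
                 params_hbo = params_hbo, params_hbr = params_hbr),
            class = "riemnirs_block_config")
}

#' Assemble the block-diagonal "super kernel" feature matrix
#'
#' Estimates one kernel per chromophore under its own estimator and
#' shrinkage, and places them on the diagonal of a `2c x 2c` matrix with all
#' cross-chromophore entries exactly zero — the direct sum
#' `K_HbO (+) K_HbR`.
#'
#' @param x_hbo,x_hbr epochs (or `c x t` matrices) for HbO and HbR; equal
#'   channel counts and sample counts.
#' @param cfg a [block_kernel_config()].
#' @return `2c x 2c` SPD matrix.
#' @export
build_block_kernel <- function(x_hbo, x_hbr, cfg = block_kernel_config()) {
  Vo <- .epoch_values(x_hbo)
  Vr <- .epoch_values(x_hbr)
  if (nrow(Vo) != nrow(Vr)) {
    stop("HbO and HbR must have the same channel count", call. = FALSE)
  }
  if (ncol(Vo) != ncol(Vr)) {
    stop("HbO and HbR must have the same sample count", call. = FALSE)
  }
  Ko <- shrink(do.call(estimate_kernel,
                       c(list(Vo, estimator = cfg$kernel_hbo), cfg$params_hbo)),
               cfg$shrinkage_hbo)
  Kr <- shrink(do.call(estimate_kernel,
                       c(list(Vr, estimator = cfg$kernel_hbr), cfg$params_hbr)),
               cfg$shrinkage_hbr)
  c_ <- nrow(Vo)
  out <- matrix(0, 2 * c_, 2 * c_)
  out[seq_len(c_), seq_len(c_)] <- Ko
  out[c_ + seq_len(c_), c_ + seq_len(c_)] <- Kr
  # the block feature lives on the product manifold of its two blocks;
  # downstream geometry exploits this for exact per-block computation
  attr(out, "block_sizes") <- c(c_, c_)
  out
}

#' Assemble the full concatenated kernel matrix
#'
#' Stacks the HbO and HbR channels vertically and applies a single estimator
#' to the `2c x t` series, then shrinks. Unlike the block variant the
#' cross-chromophore entries are generally nonzero and the feature lives on
#' the full `2c(2c+1)/2`-dimensional manifold.
#'
#' @param x_hbo,x_hbr epochs (or matrices) with equal channel and sample
#'   counts.
#' @param estimator single estimator name applied to the stacked series.
#' @param alpha shrinkage intensity.
#' @param ... estimator parameters.
#' @return `2c x 2c` SPD matrix.
#' @export
build_full_kernel <- function(x_hbo, x_hbr, estimator = "scm", alpha = 0.01, ...) {
  Vo <- .epoch_values(x_hbo)
  Vr <- .epoch_values(x_hbr)
  if (nrow(Vo) != nrow(Vr)) {
    stop("HbO and HbR must have the same channel count", call. = FALSE)
  }
  if (ncol(Vo) != ncol(Vr)) {
    stop("HbO and HbR must have the same sample count", call. = FALSE)
  }
  shrink(estimate_kernel(rbind(Vo, Vr), estimator = estimator, ...), alpha)
}
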