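#' Symmetric positive-definite matrices and the affine-invariant metric
#'
#' Channel kernel and covariance matrices live on the manifold of symmetric
#' positive-definite (SPD) matrices. All Riemannian operations in this
#' package use the affine-invariant Riemannian metric (AIRM), the standard
#' choice in covariance-based brain-computer interfacing: distances are
#' invariant under congruence transforms `G %*% S %*% t(G)` for any
#' invertible `G`, which makes the downstream classifiers insensitive to
#' common linear remixing of the channels.
#'
#' @name spd-geometry
NULL

# Relative symmetry tolerance for SPD validation.
.spd_sym_tol <- 1e-10
# Eigenvalue floor guarding matrix powers of numerically semi-definite input.
.spd_eig_floor <- 1e-12

#' Validate an SPD matrix
#'
#' Checks that `S` is a square numeric matrix, symmetric to a relative
#' tolerance of `1e-10`, and has a strictly positive smallest eigenvalue.
#'
#' @param S numeric matrix to validate.
#' @param arg name used in error messages.
#' @return `S`, invisibly, if valid; otherwise an error naming the violated
#'   invariant.
#' @export
assert_spd <- function(S, arg = "S") {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S)) {
    stop(sprintf("`%s` must be a square numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(S)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  scale <- max(abs(S), .Machine$double.eps)
  if (max(abs(S - t(S))) > .spd_sym_tol * scale) {
    stop(sprintf("`%s` is not symmetric (relative tolerance %g)", arg, .spd_sym_tol),
         call. = FALSE)
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("`%s` is not positive definite (smallest eigenvalue %g <= 0)",
                 arg, min(ev)), call. = FALSE)
  }
  invisible(S)
}

is_spd <- function(S) {
  !inherits(try(assert_spd(S), silent = TRUE), "try-error")
}

# Eigendecomposition of a symmetric matrix with exact symmetrization first.
.sym_eigen <- function(S) {
  eigen((S + t(S)) / 2, symmetric = TRUE)
}

# S^p through the eigendecomposition. For negative/fractional powers the
# eigenvalues must clear the floor; failing inputs raise rather than clip.
.spd_power <- function(S, p) {
  e <- .sym_eigen(S)
  if (min(e$values) < .spd_eig_floor) {
    stop(sprintf("matrix power %g requires eigenvalues >= %g (got %g)",
                 p, .spd_eig_floor, min(e$values)), call. = FALSE)
  }
  v <- e$values^p
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Matrix logarithm of an SPD matrix
#'
#' `U diag(log lambda) U'` from the eigendecomposition. Inverse of
#' [sym_expm()].
#'
#' @param S SPD matrix.
#' @return symmetric matrix `L` with `sym_expm(L)` equal to `S`.
#' @export
sym_logm <- function(S) {
  assert_spd(S)
  e <- .sym_eigen(S)
  out <- e$vectors %*% (log(e$values) * t(e$vectors))
  (out + t(out)) / 2
}

#' Matrix exponential of a symmetric matrix
#'
#' @param V symmetric numeric matrix.
#' @return SPD matrix `U diag(exp lambda) U'`.
#' @export
sym_expm <- function(V) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) {
    stop("`V` must be a square matrix", call. = FALSE)
  }
  scale <- max(abs(V), .Machine$double.eps)
  if (max(abs(V - t(V))) > 1e-8 * scale) {
    stop("`V` is not symmetric", call. = FALSE)
  }
  e <- .sym_eigen(V)
  out <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (out + t(out)) / 2
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `d(A, B) = || logm(A^{-1/2} B A^{-1/2}) ||_F`, equivalently the root sum
#' of squared log generalized eigenvalues of `(B, A)`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return nonnegative scalar distance.
#' @export
airm_distance <- function(A, B) {
  assert_spd(A, "A")
  assert_spd(B, "B")
  if (nrow(A) != nrow(B)) {
    stop("`A` and `B` must have the same dimension", call. = FALSE)
  }
  Aih <- .spd_power(A, -0.5)
  M <- Aih %*% B %*% Aih
  ev <- .sym_eigen(M)$values
  sqrt(sum(log(ev)^2))
}

#' Geodesic between two SPD matrices
#'
#' The AIRM geodesic `A^{1/2} (A^{-1/2} B A^{-1/2})^t A^{1/2}`; `t = 0`
#' gives `A`, `t = 1` gives `B`, `t = 1/2` the geometric mean.
#'
#' @param A,B SPD matrices of equal dimension.
#' @param t interpolation parameter in `[0, 1]`.
#' @return SPD matrix on the geodesic.
#' @export
geodesic <- function(A, B, t) {
  assert_spd(A, "A")
  assert_spd(B, "B")
  if (nrow(A) != nrow(B)) {
    stop("`A` and `B` must have the same dimension", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    stop("`t` must be a scalar in [0, 1]", call. = FALSE)
  }
  Ah <- .spd_power(A, 0.5)
  Aih <- .spd_power(A, -0.5)
  mid <- .spd_power(Aih %*% B %*% Aih, t)
  out <- Ah %*% mid %*% Ah
  (out + t(out)) / 2
}

#' Fréchet (Karcher) mean of SPD matrices
#'
#' The point minimizing the sum of squared AIRM distances to the inputs,
#' computed by the standard fixed-point iteration
#' `M <- M^{1/2} expm(mean_i logm(M^{-1/2} M_i M^{-1/2})) M^{1/2}`,
#' initialized at the arithmetic mean and stopped when the Frobenius norm of
#' the tangent-space mean falls below `tol`.
#'
#' @param Ms list of SPD matrices of equal dimension.
#' @param tol convergence tolerance on the tangent-mean norm.
#' @param max_iter maximum number of fixed-point iterations; if reached
#'   without convergence the last iterate is returned with a warning and
#'   `attr(, "converged") = FALSE`.
#' @return SPD matrix with attributes `converged` and `iterations`.
#' @export
frechet_mean <- function(Ms, tol = 1e-8, max_iter = 50) {
  if (!is.list(Ms) || length(Ms) == 0) {
    stop("`Ms` must be a nonempty list of SPD matrices", call. = FALSE)
  }
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  n <- nrow(Ms[[1]])
  for (i in seq_along(Ms)) {
    assert_spd(Ms[[i]], sprintf("Ms[[%d]]", i))
    if (nrow(Ms[[i]]) != n) stop("all matrices must share one dimension", call. = FALSE)
  }
  if (length(Ms) == 1) {
    M <- Ms[[1]]
    attr(M, "converged") <- TRUE
    attr(M, "iterations") <- 0L
    return(M)
  }
  M <- Reduce(`+`, Ms) / length(Ms)
  converged <- FALSE
  it <- 0L
  step <- 1
  prev_norm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    e <- .sym_eigen(M)
    if (min(e$values) < .spd_eig_floor) {
      stop(sprintf("mean iterate lost positive definiteness (%g)",
                   min(e$values)), call. = FALSE)
    }
    sq <- sqrt(e$values)
    Mh <- e$vectors %*% (sq * t(e$vectors))
    Mih <- e$vectors %*% ((1 / sq) * t(e$vectors))
    Tm <- matrix(0, n, n)
    for (S in Ms) Tm <- Tm + sym_logm(Mih %*% S %*% Mih)
    Tm <- Tm / length(Ms)
    nrm <- sqrt(sum(Tm^2))
    if (nrm < tol) {
      converged <- TRUE
      break
    }
    # safeguard: the unit-step fixed point can cycle for widely spread
    # inputs; halve the step when the tangent norm stops decreasing and
    # let it recover geometrically while progress resumes
    if (nrm >= prev_norm) step <- step / 2 else step <- min(1, step * 1.2)
    prev_norm <- nrm
    M <- Mh %*% sym_expm(step * Tm) %*% Mh
    M <- (M + t(M)) / 2
  }
  if (!converged) {
    warning(sprintf("Fréchet mean did not converge in %d iterations", max_iter))
  }
  attr(M, "converged") <- converged
  attr(M, "iterations") <- it
  M
}

# Row-major upper-triangle index pairs (i <= j) for an n x n matrix,
# cached per dimension.
.upper_idx <- function(n) {
  i <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  j <- unlist(lapply(seq_len(n), function(k) k:n), use.names = FALSE)
  cbind(i, j)
}

# Vectorize a symmetric matrix: upper triangle row-major, off-diagonal
# entries scaled by sqrt(2) so Euclidean dot products equal Frobenius
# inner products of the matrices.
.sym_vec <- function(W) {
  n <- nrow(W)
  idx <- .upper_idx(n)
  v <- W[idx]
  off <- idx[, 1] != idx[, 2]
  v[off] <- v[off] * sqrt(2)
  v
}

# Inverse of .sym_vec().
.sym_unvec <- function(v, n) {
  idx <- .upper_idx(n)
  off <- idx[, 1] != idx[, 2]
  v[off] <- v[off] / sqrt(2)
  W <- matrix(0, n, n)
  W[idx] <- v
  W[idx[, c(2, 1)]] <- v
  W
}

#' Map an SPD matrix to the tangent space at a reference point
#'
#' Computes `W = logm(M^{-1/2} S M^{-1/2})` and vectorizes its upper
#' triangle (row-major) with off-diagonal entries scaled by `sqrt(2)`, so
#' that Euclidean geometry among tangent vectors reproduces the AIRM
#' locally: the vector norm of `tangent_map(S, M)` equals
#' `airm_distance(S, M)`.
#'
#' @param S SPD matrix to map.
#' @param M SPD reference point (typically a Fréchet mean).
#' @return numeric vector of length `n * (n + 1) / 2`.
#' @export
tangent_map <- function(S, M) {
  assert_spd(S, "S")
  assert_spd(M, "M")
  if (nrow(S) != nrow(M)) {
    stop("`S` and `M` must have the same dimension", call. = FALSE)
  }
  Mih <- .spd_power(M, -0.5)
  .sym_vec(sym_logm(Mih %*% S %*% Mih))
}

#' Dimension of an SPD manifold, optionally block-diagonal
#'
#' A full `n x n` SPD matrix has `n(n+1)/2` free parameters; constraining it
#' to a block-diagonal structure with blocks of sizes `block_sizes` reduces
#' the dimension to the sum of the per-block counts. For the dual-chromophore
#' setting with 62 channels each, the full 124-channel manifold has
#' dimension 7750 while the two-block manifold has 3906.
#'
#' @param n matrix size.
#' @param block_sizes optional integer vector of diagonal block sizes,
#'   summing to `n`.
#' @return integer manifold dimension.
#' @export
#' @examples
#' manifold_dim(124)           # 7750
#' manifold_dim(124, c(62, 62)) # 3906
manifold_dim <- function(n, block_sizes = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (is.null(block_sizes)) {
    return(as.integer(n * (n + 1) / 2))
  }
  if (any(block_sizes < 1) || any(block_sizes != round(block_sizes))) {
    stop("`block_sizes` must be positive integers", call. = FALSE)
  }
  if (sum(block_sizes) != n) {
    stop(sprintf("`block_sizes` must sum to n = %d (got %d)", n, sum(block_sizes)),
         call. = FALSE)
  }
  as.integer(sum(block_sizes * (block_sizes + 1) / 2))
}
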