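# Shared fixtures and independent oracles, built in code.

# Random SPD matrix with moderate conditioning.
rand_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n + diag(n) * 0.5
}

# Log-Euclidean distance: independent oracle for commuting cases, where it
# coincides with the affine-invariant distance.
logeuclid_distance <- function(A, B) {
  la <- riemnirs::sym_logm(A)
  lb <- riemnirs::sym_logm(B)
  sqrt(sum((la - lb)^2))
}

# Brute-force 1-D optimal transport via the simplex LP (boot::simplex):
# minimize sum_ij c_ij f_ij subject to row sums = wx, col sums = wy.
lp_wasserstein <- function(x, y, wx = NULL, wy = NULL) {
  if (is.null(wx)) wx <- rep(1 / length(x), length(x))
  if (is.null(wy)) wy <- rep(1 / length(y), length(y))
  wx <- wx / sum(wx)
  wy <- wy / sum(wy)
  nx <- length(x)
  ny <- length(y)
  cost <- as.vector(outer(x, y, function(a, b) abs(a - b)))  # f11,f21,..
  A3 <- NULL
  b3 <- NULL
  # equality constraints: row marginals then column marginals
  for (i in seq_len(nx)) {
    row <- rep(0, nx * ny)
    row[i + nx * (seq_len(ny) - 1)] <- 1
    A3 <- rbind(A3, row)
    b3 <- c(b3, wx[i])
  }
  # drop the last column-marginal constraint: it is implied by the others
  # (both marginals sum to one), and the redundancy breaks the simplex
  for (j in seq_len(ny - 1)) {
    row <- rep(0, nx * ny)
    row[(j - 1) * nx + seq_len(nx)] <- 1
    A3 <- rbind(A3, row)
    b3 <- c(b3, wy[j])
  }
  res <- boot::simplex(a = cost, A3 = A3, b3 = b3, maxi = FALSE)
  unname(res$value)
}

# Small two-class dataset of SPD matrices generated from two orthogonal
# spatial patterns; linearly separable in the tangent space.
separable_spd_set <- function(n_per_class = 10, c_ = 4, seed = 1) {
  set.seed(seed)
  u1 <- c(rep(1, c_ / 2), rep(0, c_ - c_ / 2))
  u2 <- c(rep(0, c_ / 2), rep(1, c_ - c_ / 2))
  make1 <- function(u) {
    X <- matrix(rnorm(c_ * 100, sd = 0.05), c_, 100) +
      u %o% rnorm(100)
    riemnirs::shrink(riemnirs::estimate_kernel(X, "scm"), 0.05)
  }
  feats <- c(replicate(n_per_class, make1(u1), simplify = FALSE),
             replicate(n_per_class, make1(u2), simplify = FALSE))
  labels <- rep(c("a", "b"), each = n_per_class)
  list(feats = feats, labels = labels)
}

# Compact synthetic session shared across slow tests (computed once).
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- riemnirs::make_design(seed = 7)
      p <- riemnirs::task_profiles(8, 12, seed = 7)
      s <- riemnirs::simulate_session(d, p, riemnirs::sim_config(n_channels = 12, seed = 7))
      po <- riemnirs::preprocess_recording(s$hbo)
      pr <- riemnirs::preprocess_recording(s$hbr)
      cache <<- list(session = s, hbo = po, hbr = pr, labels = po$labels)
    }
    cache
  }
})
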