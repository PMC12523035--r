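#' Synthetic dual-chromophore fNIRS sessions
#'
#' The study's recordings are not deposited, so every downstream stage is
#' exercised on simulated sessions that carry the statistical structure the
#' method assumes: eight mental tasks with distinct spatial co-activation
#' patterns, anticorrelated HbO/HbR with partially complementary structure,
#' the four-run alternating-pair design (trial durations 5/10/15 s, 20 s
#' rests, 60 s initial rest), and physiological plus measurement noise
#' (Mayer waves ~0.1 Hz, respiration ~0.3 Hz, cardiac ~1.2 Hz, 1/f and
#' white components, and a shared global nuisance component).
#'
#' @name synthetic-data
NULL

# Evaluate expr with a locally seeded RNG, restoring global state after.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Generate the alternating-pair experimental design
#'
#' Tasks are paired without replacement across runs, so each task appears
#' in exactly one run; within a run the two tasks alternate. Each trial's
#' encoding duration is drawn uniformly from {5, 10, 15} s, every trial is
#' followed by a 20 s rest, and every run starts with a 60 s rest.
#'
#' @param n_tasks number of tasks; must equal `2 * n_runs`.
#' @param n_runs number of runs.
#' @param trials_per_task_run trials of each task within its run.
#' @param seed integer seed for pairing and duration draws.
#' @param task_names optional task labels (default `task1..taskN`).
#' @return object of class `riemnirs_design`: a list with `trials` (tibble
#'   with `run`, `label`, `onset`, `duration`; onsets are session-global
#'   seconds), `run_durations` (s), and `task_names`.
#' @export
make_design <- function(n_tasks = 8, n_runs = 4, trials_per_task_run = 12,
                        seed = 1, task_names = NULL) {
  if (n_tasks %% 2 != 0) stop("`n_tasks` must be even (tasks are paired)", call. = FALSE)
  if (n_tasks != 2 * n_runs) {
    stop("`n_tasks` must equal 2 * n_runs (pairing without replacement)",
         call. = FALSE)
  }
  if (is.null(task_names)) task_names <- sprintf("task%d", seq_len(n_tasks))
  stopifnot(length(task_names) == n_tasks)
  .with_seed(seed, {
    order_tasks <- sample(task_names)
    pairs <- split(order_tasks, rep(seq_len(n_runs), each = 2))
    initial_rest <- 60
    rest <- 20
    rows <- list()
    run_durations <- numeric(n_runs)
    t_run0 <- 0
    for (r in seq_len(n_runs)) {
      pr <- pairs[[r]]
      labels <- rep(pr, times = trials_per_task_run)  # alternating
      durations <- sample(c(5, 10, 15), length(labels), replace = TRUE)
      onset <- initial_rest
      onsets <- numeric(length(labels))
      for (i in seq_along(labels)) {
        onsets[i] <- onset
        onset <- onset + durations[i] + rest
      }
      run_durations[r] <- onset + 15  # trailing pad after the final rest
      rows[[r]] <- tibble::tibble(run = r, label = labels,
                                  onset = onsets + t_run0,
                                  duration = durations)
      t_run0 <- t_run0 + run_durations[r]
    }
    trials <- dplyr::bind_rows(rows)
    structure(list(trials = trials, run_durations = run_durations,
                   task_names = task_names,
                   initial_rest = initial_rest, rest = rest),
              class = "riemnirs_design")
  })
}

#' @export
print.riemnirs_design <- function(x, ...) {
  cat(sprintf("<riemnirs_design> %d tasks, %d runs, %d trials (%.1f min total)\n",
              length(x$task_names), length(x$run_durations), nrow(x$trials),
              sum(x$run_durations) / 60))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with a positive lobe peaking near 6 s
#' and an undershoot near 16 s, normalized to unit peak.
#'
#' @param t_axis nonnegative, increasing time axis in seconds.
#' @return numeric vector of HRF values with maximum 1.
#' @export
canonical_hrf <- function(t_axis) {
  if (any(t_axis < 0) || any(diff(t_axis) <= 0)) {
    stop("`t_axis` must be nonnegative and increasing", call. = FALSE)
  }
  # shapes/rates chosen so the positive lobe peaks at (a1-1)/b1 = 6 s and
  # the undershoot at 16 s
  h <- stats::dgamma(t_axis, shape = 7, rate = 1) -
    (1 / 6) * stats::dgamma(t_axis, shape = 17, rate = 1)
  peak <- max(h)
  if (peak <= 0) stop("degenerate time axis for HRF", call. = FALSE)
  h / peak
}

#' Task activation profiles
#'
#' One spatial loading vector per task and chromophore. HbO loadings are
#' smooth random patterns scaled to unit maximum amplitude; the HbR
#' response is built downstream as
#' `hbr_scale * (1 - complementarity) * (HbO component) +
#'  complementarity * (response with the task's own HbR loading)`,
#' so `complementarity = 0` makes HbR a pure scaled copy and larger values
#' mix in genuinely different spatial structure.
#'
#' @param n_tasks number of tasks.
#' @param n_channels channels per chromophore.
#' @param hbr_scale negative scale linking HbR to HbO (default -0.3).
#' @param complementarity mixing weight in `[0, 1]` for the independent HbR
#'   pattern (default 0.3).
#' @param seed integer seed.
#' @param max_cosine pairwise cosine-similarity bound enforced between
#'   distinct task loadings (default 0.95).
#' @return object of class `riemnirs_profiles` with matrices `loading_hbo`
#'   and `loading_hbr` (`n_channels x n_tasks`).
#' @export
task_profiles <- function(n_tasks = 8, n_channels = 62, hbr_scale = -0.3,
                          complementarity = 0.3, seed = 1, max_cosine = 0.95) {
  stopifnot(hbr_scale < 0, complementarity >= 0, complementarity <= 1)
  .with_seed(seed, {
    draw_loadings <- function() {
      L <- matrix(stats::rnorm(n_channels * n_tasks), n_channels, n_tasks)
      if (n_channels >= 5) {  # smooth over channel index for spatial coherence
        k <- stats::dnorm(-2:2, sd = 1)
        k <- k / sum(k)
        L <- apply(L, 2, function(v) {
          ve <- c(rev(v[1:2]), v, rev(v[(n_channels - 1):n_channels]))
          stats::filter(ve, k, sides = 2)[2 + seq_len(n_channels)]
        })
      }
      apply(L, 2, function(v) v / max(abs(v)))
    }
    ok <- FALSE
    for (try in 1:100) {
      Lo <- draw_loadings()
      Lr <- draw_loadings()
      norms <- sqrt(colSums(Lo^2))
      cos_sim <- abs(crossprod(Lo) / outer(norms, norms))
      diag(cos_sim) <- 0
      if (max(cos_sim) < max_cosine) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not draw sufficiently distinct task loadings", call. = FALSE)
    # rank-2 co-activation subspace per task and chromophore: channel pairs
    # that fluctuate together during the task, the second-order signature
    # the kernel features read out
    coact_hbo <- list(draw_loadings(), draw_loadings())
    coact_hbr <- list(draw_loadings(), draw_loadings())
    structure(list(loading_hbo = Lo, loading_hbr = Lr,
                   coact_hbo = coact_hbo, coact_hbr = coact_hbr,
                   hbr_scale = hbr_scale, complementarity = complementarity,
                   n_tasks = n_tasks, n_channels = n_channels),
              class = "riemnirs_profiles")
  })
}

#' Simulation configuration
#'
#' @param n_channels channels per chromophore (default 62).
#' @param sample_rate sampling rate in Hz (default 3.47).
#' @param snr amplitude of the task-locked co-activation component relative
#'   to unit-scale noise; `0` yields pure noise (the evoked component is
#'   scaled with it).
#' @param evoked amplitude of the task-evoked mean response relative to the
#'   co-activation component; mean responses carry some task information
#'   (traditional channel-mean features stay above chance) but spatial
#'   co-activation dominates.
#' @param gain_sd log-scale standard deviation of the per-trial response
#'   gain (trial-to-trial hemodynamic variability).
#' @param noise named list of amplitudes: `mayer` (~0.1 Hz), `resp`
#'   (~0.3 Hz), `cardiac` (~1.2 Hz), `pink` (1/f), `white`, `global`
#'   (shared nuisance component removed by PCA regression).
#' @param seed integer seed.
#' @return object of class `riemnirs_simconfig`.
#' @export
sim_config <- function(n_channels = 62, sample_rate = 3.47, snr = 0.04,
                       evoked = 0.15, gain_sd = 1,
                       noise = list(mayer = 0.4, resp = 0.3, cardiac = 0.2,
                                    pink = 0.5, white = 0.5, global = 1),
                       seed = 1) {
  defaults <- list(mayer = 0.4, resp = 0.3, cardiac = 0.2,
                   pink = 0.5, white = 0.5, global = 1)
  noise <- utils::modifyList(defaults, as.list(noise))
  if (any(unlist(noise) < 0)) stop("noise amplitudes must be >= 0", call. = FALSE)
  if (snr < 0) stop("`snr` must be >= 0", call. = FALSE)
  if (evoked < 0) stop("`evoked` must be >= 0", call. = FALSE)
  structure(list(n_channels = n_channels, sample_rate = sample_rate,
                 snr = snr, evoked = evoked, gain_sd = gain_sd,
                 noise = noise, seed = seed),
            class = "riemnirs_simconfig")
}

# 1/f ("pink") noise: spectrally reweight white noise, unit variance.
.pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)           # physical frequency index per FFT bin
  amp <- 1 / sqrt(pmax(f, 1))
  amp[1] <- 0                   # drop DC
  x <- Re(stats::fft(W * amp, inverse = TRUE) / n)
  as.numeric(scale(x))
}

# Build the noise-only part of one run for one chromophore.
.run_noise <- function(n_channels, n_samp, fs, noise) {
  tt <- (seq_len(n_samp) - 1) / fs
  X <- matrix(stats::rnorm(n_channels * n_samp, sd = noise$white), n_channels, n_samp)
  for (i in seq_len(n_channels)) {
    X[i, ] <- X[i, ] + noise$pink * .pink_noise(n_samp)
  }
  # physiological sinusoids: shared phase, per-channel amplitude weights
  for (comp in list(c(noise$mayer, 0.1), c(noise$resp, 0.3), c(noise$cardiac, 1.2))) {
    if (comp[1] > 0 && comp[2] < fs / 2) {
      ph <- stats::runif(1, 0, 2 * pi)
      w <- abs(stats::rnorm(n_channels, 1, 0.3))
      X <- X + comp[1] * (w %o% sin(2 * pi * comp[2] * tt + ph))
    }
  }
  # shared global nuisance: one smooth time course loaded on all channels
  if (noise$global > 0) {
    g <- .pink_noise(n_samp)
    w <- abs(stats::rnorm(n_channels, 1, 0.2))
    X <- X + noise$global * (w %o% g)
  }
  X
}

#' Simulate a full dual-chromophore session
#'
#' The HbO signal of each trial is the task's spatial loading times a
#' boxcar-convolved HRF, scaled by `snr` and a per-trial lognormal gain;
#' the HbR signal mixes a scaled anticorrelated copy with an independent
#' response from the task's HbR loading according to `complementarity`.
#' Noise per run and chromophore: physiological sinusoids with random
#' phases, 1/f and white components, and a shared global nuisance
#' component. Deterministic given `cfg$seed`.
#'
#' @param design a [make_design()] result.
#' @param profiles a [task_profiles()] result with matching task count and
#'   channel count.
#' @param cfg a [sim_config()].
#' @return list with `hbo` and `hbr` (each a
#'   [continuous_recording()] spanning all runs) and `design`.
#' @export
simulate_session <- function(design, profiles, cfg = sim_config()) {
  stopifnot(inherits(design, "riemnirs_design"),
            inherits(profiles, "riemnirs_profiles"),
            inherits(cfg, "riemnirs_simconfig"))
  if (profiles$n_channels != cfg$n_channels) {
    stop("profile channel count does not match `cfg$n_channels`", call. = FALSE)
  }
  if (!all(design$trials$label %in% paste0("task", seq_len(profiles$n_tasks))) &&
      length(unique(design$trials$label)) > profiles$n_tasks) {
    stop("design uses more tasks than the profiles provide", call. = FALSE)
  }
  fs <- cfg$sample_rate
  c_ <- cfg$n_channels
  task_idx <- stats::setNames(seq_along(design$task_names), design$task_names)
  .with_seed(cfg$seed, {
    n_runs <- length(design$run_durations)
    Xo_runs <- vector("list", n_runs)
    Xr_runs <- vector("list", n_runs)
    run_offset <- c(0, cumsum(design$run_durations))
    hrf_t <- seq(0, 30, by = 1 / fs)
    hrf <- canonical_hrf(hrf_t)
    for (r in seq_len(n_runs)) {
      n_samp <- floor(design$run_durations[r] * fs)
      So <- matrix(0, c_, n_samp)   # HbO task component
      Si <- matrix(0, c_, n_samp)   # independent HbR pattern response
      tr <- design$trials[design$trials$run == r, ]
      smooth_tc <- function(n) {  # band-limited fluctuation time course
        half <- ceiling(3 * 0.75 * fs)
        kk <- stats::dnorm(seq(-half, half), sd = 0.75 * fs)
        x <- stats::rnorm(n + 2 * half)
        x <- stats::filter(x, kk / sum(kk), sides = 2)[half + seq_len(n)]
        x <- x - mean(x)
        x / max(stats::sd(x), .Machine$double.eps)
      }
      for (k in seq_len(nrow(tr))) {
        onset_local <- tr$onset[k] - run_offset[r]
        i0 <- round(onset_local * fs) + 1
        box <- rep(0, n_samp)
        box[i0:min(n_samp, i0 + round(tr$duration[k] * fs) - 1)] <- 1
        env <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_samp)]
        j <- task_idx[[tr$label[k]]]
        g_o <- stats::rlnorm(1, 0, cfg$gain_sd)
        g_i <- stats::rlnorm(1, 0, cfg$gain_sd)
        # evoked mean response plus rank-2 stochastic co-activation whose
        # spatial subspace is the task signature
        add_task <- function(S, loading, coact, g, tc1, tc2) {
          S + cfg$snr * g * (
            cfg$evoked * (loading[, j] %o% env) +
              coact[[1]][, j] %o% (tc1 * env) +
              coact[[2]][, j] %o% (tc2 * env))
        }
        So <- add_task(So, profiles$loading_hbo, profiles$coact_hbo, g_o,
                       smooth_tc(n_samp), smooth_tc(n_samp))
        Si <- add_task(Si, profiles$loading_hbr, profiles$coact_hbr, g_i,
                       smooth_tc(n_samp), smooth_tc(n_samp))
      }
      comp <- profiles$complementarity
      Sr <- profiles$hbr_scale * (1 - comp) * So + comp * Si
      Xo_runs[[r]] <- So + .run_noise(c_, n_samp, fs, cfg$noise)
      Xr_runs[[r]] <- Sr + .run_noise(c_, n_samp, fs, cfg$noise)
    }
    Xo <- do.call(cbind, Xo_runs)
    Xr <- do.call(cbind, Xr_runs)
    # re-express trial onsets on the concatenated sample grid
    ev <- design$trials
    onsets <- numeric(nrow(ev))
    samp_offset <- c(0, cumsum(vapply(Xo_runs, ncol, integer(1))))
    for (k in seq_len(nrow(ev))) {
      r <- ev$run[k]
      onsets[k] <- (ev$onset[k] - run_offset[r]) + samp_offset[r] / fs
    }
    ev$onset <- onsets
    list(
      hbo = continuous_recording(Xo, fs, ev, chromophore = "HbO"),
      hbr = continuous_recording(Xr, fs, ev, chromophore = "HbR"),
      design = design
    )
  })
}
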