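#' Signal conditioning from continuous recordings to classifier-ready epochs
#'
#' The chain is trim -> PCA global-component regression -> band filtering
#' (Gaussian low-pass + Butterworth high-pass) -> z-scoring -> fixed-window
#' epoching. Each stage is an exported function and can be bypassed in
#' [preprocess_recording()]. All stages operate on a whole continuous
#' recording; z-scoring in particular uses whole-recording statistics, not
#' per-epoch ones.
#'
#' @name preprocessing
NULL

#' Construct a continuous multichannel recording
#'
#' @param values numeric `c x T` matrix (channels by samples).
#' @param sample_rate sampling rate in Hz.
#' @param events data frame with columns `label`, `onset` (s), `duration`
#'   (s); onsets must be strictly increasing and fit inside the recording.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param channel_names optional channel labels.
#' @return object of class `riemnirs_recording`.
#' @export
continuous_recording <- function(values, sample_rate, events,
                                 chromophore = c("HbO", "HbR"),
                                 channel_names = NULL) {
  chromophore <- match.arg(chromophore)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric channels x samples matrix", call. = FALSE)
  }
  events <- tibble::as_tibble(events)
  stopifnot(all(c("label", "onset", "duration") %in% names(events)))
  if (nrow(events) > 1 && any(diff(events$onset) <= 0)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  dur_s <- ncol(values) / sample_rate
  if (nrow(events) > 0 && any(events$onset + events$duration > dur_s + 1e-9)) {
    stop("events extend past the end of the recording", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(values)))
  }
  structure(list(values = values, sample_rate = sample_rate,
                 events = events, chromophore = chromophore,
                 channel_names = channel_names),
            class = "riemnirs_recording")
}

#' @export
print.riemnirs_recording <- function(x, ...) {
  cat(sprintf("<riemnirs_recording> %s: %d channels x %d samples @ %.2f Hz, %d events\n",
              x$chromophore, nrow(x$values), ncol(x$values), x$sample_rate,
              nrow(x$events)))
  invisible(x)
}

.with_values <- function(R, values, events = R$events) {
  R$values <- values
  R$events <- events
  R
}

#' Trim a recording around its task events
#'
#' Cuts the recording to start `pre_s` seconds before the first event onset
#' and end `post_s` seconds after the last event offset, shifting onsets
#' accordingly.
#'
#' @param R a `riemnirs_recording`.
#' @param pre_s,post_s padding kept before the first onset / after the last
#'   offset, in seconds.
#' @return trimmed `riemnirs_recording`.
#' @export
trim_recording <- function(R, pre_s = 5, post_s = 15) {
  stopifnot(inherits(R, "riemnirs_recording"))
  if (nrow(R$events) == 0) return(R)
  fs <- R$sample_rate
  t0 <- max(0, R$events$onset[1] - pre_s)
  t1 <- min(ncol(R$values) / fs,
            max(R$events$onset + R$events$duration) + post_s)
  i0 <- floor(t0 * fs) + 1
  i1 <- min(ncol(R$values), ceiling(t1 * fs))
  ev <- R$events
  ev$onset <- ev$onset - (i0 - 1) / fs
  .with_values(R, R$values[, i0:i1, drop = FALSE], ev)
}

#' Remove global components by PCA regression
#'
#' Without short-separation channels, systemic physiology (heartbeat,
#' respiration, skin blood flow) shows up as a component shared across
#' channels. This stage mean-centers every channel, computes principal
#' components across channels, and regresses the first `n_components`
#' component time courses out of every channel by least squares.
#'
#' @param R a `riemnirs_recording` with `c >= 2` channels.
#' @param n_components number of leading components to remove (default 1).
#' @return recording with the global component(s) removed; channel means 0.
#' @export
pca_global_regress <- function(R, n_components = 1) {
  stopifnot(inherits(R, "riemnirs_recording"))
  X <- R$values
  if (nrow(X) < 2) stop("PCA regression needs >= 2 channels", call. = FALSE)
  if (n_components >= nrow(X)) {
    stop("`n_components` must be smaller than the channel count", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  # channels as variables: PC time courses are right singular vectors of Xc
  sv <- svd(Xc, nu = 0, nv = n_components)
  PC <- sv$v  # T x n_components, orthonormal time courses
  # least-squares removal per channel; PC columns orthonormal so the
  # projector is PC %*% t(PC)
  Xr <- Xc - (Xc %*% PC) %*% t(PC)
  Xr <- Xr - rowMeans(Xr)
  .with_values(R, Xr)
}

# sigma (in seconds) of the Gaussian smoothing kernel whose frequency
# response exp(-2 pi^2 sigma^2 f^2) is 1/2 at f = lp_hz.
.gauss_sigma_s <- function(lp_hz) sqrt(log(2) / 2) / (pi * lp_hz)

.gaussian_lowpass <- function(X, sample_rate, lp_hz) {
  sigma <- .gauss_sigma_s(lp_hz) * sample_rate  # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- half
  out <- t(apply(X, 1, function(x) {
    xe <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1]))
    stats::filter(xe, k, sides = 2)[pad + seq_along(x)]
  }))
  out
}

#' Band filtering: Butterworth high-pass plus Gaussian low-pass
#'
#' The high-pass is a zero-phase (forward-backward) Butterworth of order 2
#' at `hp_hz`; the low-pass is convolution with a Gaussian kernel whose
#' transfer function is 0.5 at `lp_hz` (half-amplitude cutoff,
#' `sigma = sqrt(log 2 / 2) / (pi * lp_hz)` seconds).
#'
#' @param R a `riemnirs_recording`.
#' @param hp_hz high-pass cutoff in Hz (default 0.01).
#' @param lp_hz low-pass half-amplitude cutoff in Hz (default 0.4).
#' @return filtered recording.
#' @export
bandfilter <- function(R, hp_hz = 0.01, lp_hz = 0.4) {
  stopifnot(inherits(R, "riemnirs_recording"))
  fs <- R$sample_rate
  if (lp_hz >= fs / 2) stop("`lp_hz` must be below the Nyquist frequency", call. = FALSE)
  if (hp_hz >= lp_hz) stop("`hp_hz` must be below `lp_hz`", call. = FALSE)
  bf <- signal::butter(2, hp_hz / (fs / 2), type = "high")
  # demean and reflect-pad before the forward-backward pass: the filter's
  # settling time at a 0.01 Hz cutoff is on the order of the recording
  # length, and unpadded filtfilt leaks the step transient into the data
  pad <- min(ncol(R$values) - 1, ceiling(fs / hp_hz))
  X <- t(apply(R$values, 1, function(x) {
    x <- x - mean(x)
    xe <- c(rev(x[seq_len(pad)]), x, rev(x)[seq_len(pad)])
    as.numeric(signal::filtfilt(bf, xe))[pad + seq_along(x)]
  }))
  X <- .gaussian_lowpass(X, fs, lp_hz)
  .with_values(R, X)
}

#' Z-score each channel over the whole recording
#'
#' Population (1/N) standard deviation; applied to the trimmed continuous
#' recording before epoching so every epoch shares one scale.
#'
#' @param R a `riemnirs_recording`.
#' @return recording with channel means 0 and standard deviations 1.
#' @export
zscore_channels <- function(R) {
  stopifnot(inherits(R, "riemnirs_recording"))
  X <- R$values
  m <- rowMeans(X)
  s <- sqrt(rowMeans((X - m)^2))
  bad <- which(s == 0)
  if (length(bad) > 0) {
    stop(sprintf("channel(s) with zero variance cannot be z-scored: %s",
                 paste(R$channel_names[bad], collapse = ", ")), call. = FALSE)
  }
  .with_values(R, (X - m) / s)
}

#' Cut fixed-length epochs at event onsets
#'
#' Every epoch spans cue onset to `window_s` seconds post-cue and has
#' exactly `floor(window_s * sample_rate)` samples regardless of the
#' event's nominal duration, so downstream covariance estimates use equal
#' amounts of data per trial. Onsets are snapped to the nearest sample.
#'
#' @param R a `riemnirs_recording`.
#' @param window_s epoch window length in seconds (default 10).
#' @return list with `epochs` (list of [multichannel_epoch()]) and `labels`
#'   (character vector in event order).
#' @export
epoch_trials <- function(R, window_s = 10) {
  stopifnot(inherits(R, "riemnirs_recording"))
  fs <- R$sample_rate
  n_samp <- floor(window_s * fs)
  Tn <- ncol(R$values)
  epochs <- vector("list", nrow(R$events))
  for (i in seq_len(nrow(R$events))) {
    i0 <- round(R$events$onset[i] * fs) + 1
    i1 <- i0 + n_samp - 1
    if (i1 > Tn) {
      stop(sprintf("event %d ('%s' at %.1f s): window extends past recording end",
                   i, R$events$label[i], R$events$onset[i]), call. = FALSE)
    }
    epochs[[i]] <- multichannel_epoch(R$values[, i0:i1, drop = FALSE],
                                      chromophore = R$chromophore,
                                      sample_rate = fs)
  }
  list(epochs = epochs, labels = as.character(R$events$label))
}

#' Run the full preprocessing chain on one recording
#'
#' Trim -> PCA global regression -> band filter -> z-score -> epoch, each
#' stage bypassable.
#'
#' @param R a `riemnirs_recording`.
#' @param trim,pca,filter,zscore logical flags enabling each stage.
#' @param n_components,hp_hz,lp_hz,window_s stage parameters, see the
#'   individual stage functions.
#' @return as [epoch_trials()].
#' @export
preprocess_recording <- function(R, trim = TRUE, pca = TRUE, filter = TRUE,
                                 zscore = TRUE, n_components = 1,
                                 hp_hz = 0.01, lp_hz = 0.4, window_s = 10) {
  if (trim) R <- trim_recording(R)
  if (pca) R <- pca_global_regress(R, n_components = n_components)
  if (filter) R <- bandfilter(R, hp_hz = hp_hz, lp_hz = lp_hz)
  if (zscore) R <- zscore_channels(R)
  epoch_trials(R, window_s = window_s)
}
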