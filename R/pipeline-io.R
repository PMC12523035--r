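#' Pipeline orchestration and the on-disk epoch store
#'
#' The epoch store persists one session as raw little-endian float64
#' matrices (one file per chromophore) plus a JSON sidecar carrying the
#' schema version, sample rate, channel names, and the event table. The
#' pipeline runner binds simulate -> preprocess -> feature build ->
#' (optional grid search) -> cross-validation -> report, with one global
#' seed split into per-stage child seeds.
#'
#' @name pipeline-io
NULL

.store_schema <- 1L

# Deterministic per-stage child seeds from one global seed; keeps every
# stage independently re-runnable. Values stay below 2^31.
.child_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, preprocess = 23L, features = 37L,
            cv = 53L, permutation = 71L, bootstrap = 89L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.double(seed) * 1009 + offs[[stage]]) %% 2147483647)
}

#' Write a session to an epoch store directory
#'
#' @param session list with `hbo` and `hbr` recordings (as returned by
#'   [simulate_session()]).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epoch_store <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (chrom in c("hbo", "hbr")) {
    R <- session[[chrom]]
    con <- file(file.path(path, paste0(chrom, ".f64")), "wb")
    writeBin(as.numeric(t(R$values)), con, size = 8, endian = "little")
    close(con)
  }
  meta <- list(
    schema = .store_schema,
    sample_rate = session$hbo$sample_rate,
    n_channels = nrow(session$hbo$values),
    n_samples = ncol(session$hbo$values),
    channel_names = session$hbo$channel_names,
    events = session$hbo$events
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a session from an epoch store directory
#'
#' @param path directory written by [write_epoch_store()].
#' @return list with `hbo` and `hbr` recordings.
#' @export
read_epoch_store <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop(sprintf("'%s' is not an epoch store (no meta.json)", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema), .store_schema)) {
    stop(sprintf("unsupported epoch store schema %s", meta$schema), call. = FALSE)
  }
  events <- tibble::as_tibble(meta$events)
  out <- list()
  for (chrom in c("hbo", "hbr")) {
    fp <- file.path(path, paste0(chrom, ".f64"))
    n <- meta$n_channels * meta$n_samples
    con <- file(fp, "rb")
    v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
    close(con)
    if (length(v) != n) {
      stop(sprintf("'%s' is truncated (%d of %d values)", fp, length(v), n),
           call. = FALSE)
    }
    out[[chrom]] <- continuous_recording(
      matrix(v, meta$n_channels, meta$n_samples, byrow = TRUE),
      meta$sample_rate, events,
      chromophore = if (chrom == "hbo") "HbO" else "HbR",
      channel_names = meta$channel_names)
  }
  out
}

#' Run the full decoding pipeline on a synthetic session
#'
#' simulate (or load) -> preprocess -> per-model feature build -> optional
#' per-model grid search -> repeated stratified cross-validation ->
#' evaluation report. Identical config and seed give identical reports.
#'
#' @param models character vector of model names from [model_registry()].
#' @param configs optional named list mapping model names to config lists
#'   (fixed configuration) or to lists of config lists (grid to search).
#' @param session optional preexisting session (from [simulate_session()]
#'   or [read_epoch_store()]); simulated when missing.
#' @param sim a [sim_config()] used when simulating.
#' @param design_args list of arguments to [make_design()].
#' @param cv a [cv_spec()].
#' @param window_s epoch window in seconds.
#' @param seed global seed; split into per-stage child seeds.
#' @param verbose print per-stage progress.
#' @return object of class `riemnirs_report`: a tibble with one row per
#'   model (`model`, `type`, `mean_accuracy`, `sd_accuracy`, bootstrap
#'   `ci_low`/`ci_high`), with per-model accuracy vectors and confusion
#'   matrices in attributes.
#' @export
run_pipeline <- function(models = model_registry()$model, configs = list(),
                         session = NULL, sim = NULL,
                         design_args = list(), cv = NULL,
                         window_s = 10, seed = 1, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  reg <- model_registry()
  unknown <- setdiff(models, reg$model)
  if (length(unknown) > 0) {
    stop(sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(sim)) sim <- sim_config(seed = .child_seed(seed, "simulate"))
  if (is.null(cv)) cv <- cv_spec(seed = .child_seed(seed, "cv"))
  if (is.null(session)) {
    say("simulate: %d channels @ %.2f Hz", sim$n_channels, sim$sample_rate)
    design <- do.call(make_design,
                      utils::modifyList(list(seed = .child_seed(seed, "simulate")),
                                        design_args))
    profiles <- task_profiles(n_tasks = length(design$task_names),
                              n_channels = sim$n_channels,
                              seed = .child_seed(seed, "simulate"))
    session <- simulate_session(design, profiles, sim)
  }
  say("preprocess: %d events", nrow(session$hbo$events))
  po <- preprocess_recording(session$hbo, window_s = window_s)
  pr <- preprocess_recording(session$hbr, window_s = window_s)
  stopifnot(identical(po$labels, pr$labels))
  labels <- po$labels
  rows <- vector("list", length(models))
  acc_list <- list()
  conf_list <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    cfg <- configs[[m]]
    is_grid <- !is.null(cfg) && is.list(cfg) && length(cfg) > 0 &&
      all(vapply(cfg, is.list, logical(1))) && is.null(names(cfg))
    if (is_grid) {
      say("grid search: %s over %d configurations", m, length(cfg))
      gs <- grid_search(m, cfg, po$epochs, pr$epochs, labels, cv)
      spec <- gs$best_spec
    } else {
      spec <- model_spec(m, if (is.null(cfg)) list() else cfg)
    }
    say("cross-validate: %s", m)
    feats <- build_features(po$epochs, pr$epochs, spec)
    res <- cross_validate(spec, feats, labels, cv)
    bs <- bootstrap_mean_ci(res$accuracies,
                            seed = .child_seed(seed, "bootstrap"))
    rows[[i]] <- tibble::tibble(
      model = m, type = reg$type[reg$model == m],
      mean_accuracy = mean(res$accuracies),
      sd_accuracy = stats::sd(res$accuracies),
      ci_low = bs$ci_low, ci_high = bs$ci_high)
    acc_list[[m]] <- res$accuracies
    conf_list[[m]] <- res$confusion
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "accuracies") <- acc_list
  attr(report, "confusions") <- conf_list
  attr(report, "labels") <- labels
  attr(report, "seed") <- seed
  class(report) <- c("riemnirs_report", class(report))
  report
}

#' @method glance riemnirs_report
#' @export
glance.riemnirs_report <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    n_trials = length(attr(x, "labels")),
    n_classes = length(unique(attr(x, "labels"))),
    best_model = x$model[which.max(x$mean_accuracy)],
    best_accuracy = max(x$mean_accuracy))
}

#' @method tidy riemnirs_report
#' @export
tidy.riemnirs_report <- function(x, ...) {
  accs <- attr(x, "accuracies")
  purrr::map_dfr(names(accs), function(m) {
    tibble::tibble(model = m, fold = seq_along(accs[[m]]),
                   accuracy = accs[[m]])
  })
}

#' Compare the best Riemannian model against the traditional baselines
#'
#' Computes the relative improvement score of the best Riemannian model
#' over each traditional baseline in a report, plus a paired t-test across
#' matched folds.
#'
#' @param report a [run_pipeline()] report containing at least one model of
#'   each type.
#' @return tibble with one row per traditional baseline: `baseline`,
#'   `baseline_accuracy`, `riemannian_model`, `riemannian_accuracy`, `ris`,
#'   `t`, `p`.
#' @export
compare_models <- function(report) {
  stopifnot(inherits(report, "riemnirs_report"))
  accs <- attr(report, "accuracies")
  riem <- report[report$type == "riemannian", ]
  trad <- report[report$type == "traditional", ]
  if (nrow(riem) == 0 || nrow(trad) == 0) {
    stop("report must contain both Riemannian and traditional models",
         call. = FALSE)
  }
  best <- riem$model[which.max(riem$mean_accuracy)]
  purrr::map_dfr(trad$model, function(b) {
    tt <- paired_t(accs[[best]], accs[[b]])
    tibble::tibble(
      baseline = b,
      baseline_accuracy = mean(accs[[b]]),
      riemannian_model = best,
      riemannian_accuracy = mean(accs[[best]]),
      ris = relative_improvement(mean(accs[[b]]), mean(accs[[best]])),
      t = tt$t, p = tt$p)
  })
}
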