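# Run configuration and the end-to-end pipeline:
# simulate (or ingest) -> preprocess -> features -> scale/balance ->
# reduce -> classify -> report.

#' Build a run configuration
#'
#' All knobs of the pipeline in one serialisable list. Unknown fields are
#' rejected, and the effective configuration (plus its hash) is persisted
#' beside the outputs of every run.
#'
#' @param seed Master seed for the whole run.
#' @param out_dir Report output directory.
#' @param input_dir Optional directory of recorded data (see
#'   [read_cohort()]); when NULL, a synthetic cohort is generated.
#' @param cohort List: `n_healthy`, `n_ataxic`, `severity_range`.
#' @param generator Named overrides for [gait_params()].
#' @param effects Named overrides for [effect_sizes()].
#' @param preprocessing List: `min_contacts`, `max_contacts`, `window_s`,
#'   `heading_rate_threshold_deg_s`, `heading_cutoff_hz`, `min_speed`,
#'   `contact_height_fraction`, `speed_threshold`, `smooth_samples`.
#' @param scaling Scaling method name.
#' @param balancing List: `method`, `k_neighbors`, `noise_scale`.
#' @param reducers Reducer names for the grid.
#' @param classifiers Classifier names for the grid.
#' @param reducer_args List: `perplexity`, `n_neighbors`, `min_dist`.
#' @param hyper Classifier hyperparameter overrides.
#' @param cv List: `kind`, `mode` (leakage regime).
#' @param surface List: `classifiers`, `reducer`, `resolution`.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L,
                       out_dir = "ataxgait_report",
                       input_dir = NULL,
                       cohort = list(),
                       generator = list(),
                       effects = list(),
                       preprocessing = list(),
                       scaling = "zscore",
                       balancing = list(),
                       reducers = c("pca", "tsne", "umap"),
                       classifiers = classifier_names(),
                       reducer_args = list(),
                       hyper = list(),
                       cv = list(),
                       surface = list()) {
  merge_known <- function(defaults, given, what) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) stopf("unknown %s field(s): %s", what,
                               paste(unknown, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input_dir = input_dir,
    cohort = merge_known(list(n_healthy = 20L, n_ataxic = 23L,
                              severity_range = c(0.25, 1)),
                         cohort, "cohort"),
    generator = merge_known(formals_defaults(gait_params), generator,
                            "generator"),
    effects = merge_known(formals_defaults(effect_sizes), effects,
                          "effects"),
    preprocessing = merge_known(
      list(min_contacts = 4L, max_contacts = 16L, window_s = 0.5,
           heading_rate_threshold_deg_s = 45, heading_cutoff_hz = 0.5,
           min_speed = 0.1, contact_height_fraction = 0.1,
           speed_threshold = 0.05, smooth_samples = 5L),
      preprocessing, "preprocessing"),
    scaling = match.arg(scaling, c("zscore", "rescale", "mean_norm",
                                   "none")),
    balancing = merge_known(list(method = "smote", k_neighbors = 5L,
                                 noise_scale = 0.05),
                            balancing, "balancing"),
    reducers = reducers,
    classifiers = classifiers,
    reducer_args = merge_known(list(perplexity = 30, n_neighbors = 15,
                                    min_dist = 0.1),
                               reducer_args, "reducer_args"),
    hyper = merge_known(default_hyperparameters(), hyper, "hyper"),
    cv = merge_known(list(kind = "holdout_60_40", mode = "paper"), cv,
                     "cv"),
    surface = merge_known(list(classifiers = "Random Forest",
                               reducer = "tsne", resolution = 100L),
                          surface, "surface")
  )
  class(cfg) <- "run_config"
  cfg
}

formals_defaults <- function(fn) {
  f <- formals(fn)
  lapply(f[!vapply(f, is.symbol, TRUE)], eval, envir = baseenv())
}

#' Save / load a run configuration as YAML
#'
#' `load_run_config()` rebuilds the configuration through [run_config()],
#' so files containing unknown keys are rejected.
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `save_run_config()` the path; `load_run_config()` a
#'   `run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> features ->
#' scale/balance -> reduce -> classify -> report, logging stage timings and
#' row counts. Any stage failure aborts with the stage name. Reruns with an
#' identical configuration produce byte-identical report bundles.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage log messages.
#' @return Invisible list: `features`, `grid`, `severity`, `bundle`,
#'   `config`, `hash`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    if (!quiet) {
      message(sprintf("[%s] %.1f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    out
  }
  cohort <- log_stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_cohort(config$input_dir)
    } else {
      generate_cohort(config$cohort$n_healthy, config$cohort$n_ataxic,
                      config$cohort$severity_range,
                      do.call(gait_params, config$generator),
                      do.call(effect_sizes, config$effects),
                      seed = config$seed)
    }
  })
  pp <- config$preprocessing
  features <- log_stage("features", {
    cohort_features(
      cohort, min_contacts = pp$min_contacts,
      max_contacts = pp$max_contacts,
      turn_args = list(window_s = pp$window_s,
                       heading_rate_threshold_deg_s =
                         pp$heading_rate_threshold_deg_s,
                       heading_cutoff_hz = pp$heading_cutoff_hz,
                       min_speed = pp$min_speed),
      contact_args = list(contact_height_fraction =
                            pp$contact_height_fraction,
                          speed_threshold = pp$speed_threshold,
                          smooth_samples = pp$smooth_samples))
  })
  if (!quiet) message(sprintf("  %d segments from %d recordings",
                              nrow(features), length(cohort)))
  grid <- log_stage("evaluate", {
    bal_extra <- switch(config$balancing$method,
      smote = list(k_neighbors = config$balancing$k_neighbors),
      noise = list(noise_scale = config$balancing$noise_scale),
      list())
    suppressMessages(evaluate_grid(
      features,
      reducers = config$reducers,
      classifiers = config$classifiers,
      scheme = cv_scheme(config$cv$kind, seed = derive_seed(config$seed,
                                                            17L)),
      seed = config$seed,
      scaling = config$scaling,
      balancing = config$balancing$method,
      mode = config$cv$mode,
      hyper = config$hyper,
      reducer_args = config$reducer_args))
  })
  severity <- log_stage("severity", {
    emb <- grid$embeddings[[config$surface$reducer]]
    if (is.null(emb)) {
      scaled <- scale_features(features, config$scaling)
      emb <- do.call(reduce_features,
                     c(list(scaled, config$surface$reducer,
                            seed = derive_seed(config$seed, 99L)),
                       config$reducer_args))
    }
    if (length(unique(features$severity)) >= 3L) {
      severity_report(emb, features$severity)
    } else NULL
  })
  bundle <- log_stage("report", {
    hashed_cfg <- unclass(config)
    hashed_cfg$out_dir <- NULL  # output location must not affect the bundle
    render_reports(grid, severity, config$out_dir,
                   config = hashed_cfg,
                   surface_classifiers = config$surface$classifiers,
                   surface_reducer = config$surface$reducer,
                   surface_resolution = config$surface$resolution)
  })
  invisible(list(features = features, grid = grid, severity = severity,
                 bundle = bundle, config = config, hash = bundle$hash))
}
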