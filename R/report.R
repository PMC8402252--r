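# Report rendering: metric tables, embedding scatters, decision-surface
# grids and a JSON manifest, every file stamped with the run-config hash.

#' Hash a run configuration
#'
#' MD5 of the canonical JSON serialisation; used to stamp every output file
#' so a stored bundle can be re-validated against its configuration.
#'
#' @param config Any serialisable list.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a hash-stamped CSV written by [render_reports()]
#'
#' @param path CSV path.
#' @return Data frame; the stamp is available as `attr(, "config_hash")`.
#' @export
read_csv_hashed <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "config_hash") <- sub("^# config_hash ", "", first)
  df
}

#' Render the report bundle of an evaluation run
#'
#' Writes, under `out_dir`: one `metrics_<reducer>.csv` per reducer
#' (Name/Accuracy/Sensitivity/Specificity rows per classifier), a
#' `grid_accuracy.csv` (classifier x reducer), one `embedding_<reducer>.csv`
#' scatter per joint embedding (paper mode) with class, participant and
#' severity columns, optional decision-surface grids, a
#' `severity_scatter.csv`, and `manifest.json` recording the config hash,
#' file list, severity statistics and the leakage note. Every CSV starts
#' with a `# config_hash` stamp. An empty grid is an error before any file
#' is touched.
#'
#' @param grid A `gait_grid` from [evaluate_grid()].
#' @param severity A `severity_report` or NULL.
#' @param out_dir Output directory (created).
#' @param config Run configuration to hash; defaults to the grid's own
#'   provenance.
#' @param surface_classifiers Classifier names to render decision surfaces
#'   for (trained on the full joint embedding of `surface_reducer`).
#' @param surface_reducer Reducer whose embedding backs the surfaces.
#' @param surface_resolution Grid nodes per axis.
#' @return Invisible list: `files` written and `hash`.
#' @export
render_reports <- function(grid, severity = NULL, out_dir,
                           config = NULL,
                           surface_classifiers = "Random Forest",
                           surface_reducer = "tsne",
                           surface_resolution = 100L) {
  stopifnot(inherits(grid, "gait_grid"))
  if (is.null(grid$cells) || nrow(grid$cells) == 0L) {
    stopf("empty evaluation grid: nothing to render")
  }
  if (file.exists(out_dir) && !dir.exists(out_dir)) {
    stopf("out_dir exists and is not a directory")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s",
                                  out_dir)
  config <- config %||% list(seed = grid$seed, scheme = grid$scheme$kind,
                             mode = grid$mode,
                             provenance = grid$provenance[c("scaling",
                                                            "balancing",
                                                            "hyper")])
  hash <- config_hash(config)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_csv_hashed(df, p, hash)
    files <<- c(files, name)
  }

  for (red in unique(grid$cells$reducer)) {
    sub <- grid$cells[grid$cells$reducer == red, ]
    emit(data.frame(Name = sub$classifier, Accuracy = sub$accuracy,
                    Sensitivity = sub$sensitivity,
                    Specificity = sub$specificity),
         sprintf("metrics_%s.csv", red))
  }
  acc <- accuracy_matrix(grid)
  emit(data.frame(Condition = rownames(acc), as.data.frame(acc),
                  check.names = FALSE),
       "grid_accuracy.csv")

  feats <- grid$features
  for (red in names(grid$embeddings)) {
    co <- grid$embeddings[[red]]$coordinates
    emit(data.frame(segment_id = feats$segment_id %||%
                      seq_len(nrow(co)),
                    dim1 = co[, 1], dim2 = co[, 2],
                    label = feats$label,
                    participant_id = feats$participant_id,
                    severity = feats$severity),
         sprintf("embedding_%s.csv", red))
  }

  if (length(surface_classifiers) && surface_reducer %in%
        names(grid$embeddings)) {
    emb <- grid$embeddings[[surface_reducer]]
    for (cl in surface_classifiers) {
      model <- fit_classifier(cl, emb$coordinates, feats$label,
                              seed = derive_seed(grid$seed, 555L),
                              hyper = grid$provenance$hyper)
      surf <- decision_surface(model, emb, surface_resolution)
      long <- expand.grid(x = surf$x, y = surf$y)
      long$label <- as.character(surf$labels)
      emit(long, sprintf("surface_%s_%s.csv", surface_reducer,
                         gsub("\\s+", "_", tolower(cl))))
    }
  }

  sev_stats <- NULL
  if (!is.null(severity)) {
    stopifnot(inherits(severity, "severity_report"))
    emit(data.frame(dim1 = severity$coordinates[, 1],
                    dim2 = severity$coordinates[, 2],
                    severity = severity$severities),
         "severity_scatter.csv")
    sev_stats <- list(rank_correlation = severity$rank_correlation,
                      distance_ratio = severity$distance_ratio)
  }

  manifest <- list(config_hash = hash, files = files,
                   n_segments = nrow(feats),
                   scheme = grid$scheme$kind, mode = grid$mode,
                   leakage_warning = grid$provenance$leakage_warning,
                   severity = sev_stats, config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(list(files = c(files, "manifest.json"), hash = hash))
}
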