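# The reducer x classifier evaluation grid.
#
# Two leakage regimes are provided. "paper" mode embeds all segments jointly
# before splitting, mirroring the common (and optimistic) practice for
# non-parametric embeddings like t-SNE; a leakage warning is attached to the
# result. "strict" mode fits scaling, balancing and the reducer on training
# rows only and places test rows by out-of-sample transform.

#' Evaluate the reducer x classifier grid
#'
#' Runs every combination of the requested 2-D reducers and registered
#' classifiers under one cross-validation scheme, computing pooled-test
#' accuracy, sensitivity and specificity per cell. Balancing is applied to
#' training rows only in both modes. Cell failures are flagged (NA metrics,
#' message recorded) and never abort the rest of the grid.
#'
#' @param features Feature data frame from [cohort_features()] (metadata
#'   columns plus the feature columns).
#' @param reducers Character subset of `c("pca", "tsne", "umap")`.
#' @param classifiers Character subset of [classifier_names()].
#' @param scheme A [cv_scheme()].
#' @param seed Master integer seed; the full grid re-runs bit-identically
#'   under the same seed.
#' @param scaling Scaling method for [scale_features()].
#' @param balancing Balancing method for [balance_classes()] (`"none"` to
#'   disable).
#' @param mode `"paper"` (joint embedding, leakage warning) or `"strict"`
#'   (training-only fits).
#' @param hyper Classifier hyperparameter overrides.
#' @param reducer_args Extra arguments for [reduce_features()] (perplexity,
#'   n_neighbors, min_dist).
#' @param positive_class Label treated as positive (default `"ataxic"`).
#' @return A `gait_grid` object; see [print.gait_grid()].
#' @export
evaluate_grid <- function(features,
                          reducers = c("pca", "tsne", "umap"),
                          classifiers = classifier_names(),
                          scheme = cv_scheme("holdout_60_40"),
                          seed = 1L,
                          scaling = "zscore",
                          balancing = "smote",
                          mode = c("paper", "strict"),
                          hyper = list(),
                          reducer_args = list(),
                          positive_class = "ataxic") {
  mode <- match.arg(mode)
  reducers <- match.arg(reducers, c("pca", "tsne", "umap"),
                        several.ok = TRUE)
  stopifnot(all(classifiers %in% classifier_names(TRUE)))
  folds <- cv_split(features, scheme)
  leakage_warning <- if (mode == "paper") {
    paste("paper mode: scaling and embedding were fitted on all segments",
          "before splitting; reported metrics are optimistic")
  } else NA_character_
  if (mode == "paper") message(leakage_warning)

  embeddings <- list()
  cells <- list()
  details <- list()
  for (r in seq_along(reducers)) {
    red <- reducers[r]
    red_seed <- derive_seed(seed, 1000L + r)
    fold_data <- tryCatch({
      if (mode == "paper") {
        scaled <- scale_features(features, scaling)
        emb <- do.call(reduce_features,
                       c(list(scaled, red, seed = red_seed), reducer_args))
        embeddings[[red]] <- emb
        lapply(folds, function(fold) {
          paper_fold_data(features, emb, fold, balancing,
                          derive_seed(red_seed, fold$train[1]))
        })
      } else {
        lapply(seq_along(folds), function(fi) {
          strict_fold_data(features, folds[[fi]], red, scaling, balancing,
                           derive_seed(red_seed, fi), reducer_args)
        })
      }
    }, error = function(e) structure(conditionMessage(e),
                                     class = "fold_failure"))
    for (ci in seq_along(classifiers)) {
      cl <- classifiers[ci]
      cell_seed <- derive_seed(seed, 10000L + 100L * r + ci)
      cell <- tryCatch({
        if (inherits(fold_data, "fold_failure")) {
          stopf("reducer preparation failed: %s", unclass(fold_data))
        }
        preds <- character(0); truths <- character(0)
        fold_pred <- vector("list", length(fold_data))
        for (fi in seq_along(fold_data)) {
          fd <- fold_data[[fi]]
          p <- fit_predict(cl, fd$train_x, fd$train_y, fd$test_x,
                           seed = derive_seed(cell_seed, fi),
                           hyper = hyper)
          fold_pred[[fi]] <- list(predictions = as.character(p),
                                  truths = as.character(fd$test_y),
                                  test_rows = fd$test_rows)
          preds <- c(preds, as.character(p))
          truths <- c(truths, as.character(fd$test_y))
        }
        cm <- confusion_metrics(truths, preds, positive_class)
        list(metrics = cm, folds = fold_pred, error = NA_character_)
      }, error = function(e) {
        list(metrics = list(accuracy = NA_real_, sensitivity = NA_real_,
                            specificity = NA_real_),
             folds = list(), error = conditionMessage(e))
      })
      cells[[length(cells) + 1L]] <- data.frame(
        reducer = red, classifier = cl,
        accuracy = cell$metrics$accuracy,
        sensitivity = cell$metrics$sensitivity,
        specificity = cell$metrics$specificity,
        error = cell$error, stringsAsFactors = FALSE)
      details[[paste(red, cl, sep = "|")]] <- cell$folds
    }
  }
  structure(list(
    cells = do.call(rbind, cells),
    details = details,
    embeddings = embeddings,
    scheme = scheme, mode = mode, seed = seed,
    provenance = list(scaling = scaling, balancing = balancing,
                      hyper = utils::modifyList(default_hyperparameters(),
                                                hyper),
                      leakage_warning = leakage_warning),
    features = features,
    positive_class = positive_class
  ), class = "gait_grid")
}

# fold data in paper mode: joint embedding, balancing on training rows only
paper_fold_data <- function(features, emb, fold, balancing, seed) {
  coords <- emb$coordinates
  bal_df <- data.frame(label = features$label[fold$train],
                       dim1 = coords[fold$train, 1],
                       dim2 = coords[fold$train, 2],
                       stringsAsFactors = FALSE)
  bal <- balance_classes(bal_df, balancing, seed = seed)
  list(train_x = as.matrix(bal[, c("dim1", "dim2")]),
       train_y = bal$label,
       test_x = coords[fold$test, , drop = FALSE],
       test_y = features$label[fold$test],
       test_rows = fold$test)
}

# fold data in strict mode: scaling, balancing and reducer from train only
strict_fold_data <- function(features, fold, reducer, scaling, balancing,
                             seed, reducer_args = list()) {
  train_tab <- features[fold$train, , drop = FALSE]
  scaled <- scale_features(train_tab, scaling)  # parameters from train only
  train_scaled <- train_tab
  train_scaled[, colnames(scaled$matrix)] <- scaled$matrix
  bal <- balance_classes(train_scaled, balancing,
                         seed = derive_seed(seed, 1L))
  emb <- do.call(reduce_features,
                 c(list(as_feature_matrix(bal), reducer,
                        seed = derive_seed(seed, 2L)),
                   reducer_args))
  test_m <- apply_scaling(scaled, features[fold$test, , drop = FALSE])
  list(train_x = emb$coordinates,
       train_y = bal$label,
       test_x = embed_transform(emb, test_m),
       test_y = features$label[fold$test],
       test_rows = fold$test)
}

#' @export
print.gait_grid <- function(x, digits = 2, ...) {
  cat(sprintf("<gait_grid> %s, %s mode, seed %d\n", x$scheme$kind, x$mode,
              x$seed))
  acc <- accuracy_matrix(x)
  print(round(acc, digits))
  if (any(!is.na(x$cells$error))) {
    cat("flagged cells:\n")
    bad <- x$cells[!is.na(x$cells$error), ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s x %s: %s\n", bad$reducer[i], bad$classifier[i],
                  bad$error[i]))
    }
  }
  invisible(x)
}

#' Accuracy matrix of a grid (classifiers x reducers)
#'
#' @param grid A `gait_grid`.
#' @return Numeric matrix, rows = classifiers, columns = reducers.
#' @export
accuracy_matrix <- function(grid) {
  cls <- unique(grid$cells$classifier)
  red <- unique(grid$cells$reducer)
  m <- matrix(NA_real_, length(cls), length(red),
              dimnames = list(cls, toupper(red)))
  for (i in seq_len(nrow(grid$cells))) {
    m[grid$cells$classifier[i], toupper(grid$cells$reducer[i])] <-
      grid$cells$accuracy[i]
  }
  m
}

#' @export
summary.gait_grid <- function(object, ...) {
  cells <- object$cells
  cat(sprintf("grid of %d cells (%s, %s mode)\n", nrow(cells),
              object$scheme$kind, object$mode))
  if (!is.na(object$provenance$leakage_warning)) {
    cat("note:", object$provenance$leakage_warning, "\n")
  }
  print(cells[order(-cells$accuracy),
              c("reducer", "classifier", "accuracy", "sensitivity",
                "specificity")],
        row.names = FALSE, digits = 3)
  invisible(cells)
}

#' @export
plot.gait_grid <- function(x, ...) {
  m <- accuracy_matrix(x)
  op <- graphics::par(mar = c(5, 9, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(25, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Grid accuracy", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (is.finite(m[i, j])) {
      graphics::text(j, i, sprintf("%.2f", m[i, j]), cex = 0.8)
    }
  }
  invisible(x)
}

#' Label a dense grid over an embedding with a trained classifier
#'
#' Builds a rectangular `grid_resolution`-squared lattice over the bounding
#' box of the embedding coordinates (plus a 5% margin) and labels each node
#' with the classifier's prediction — the data behind a decision-surface
#' plot.
#'
#' @param model A fitted `gait_classifier` (trained on 2-D coordinates).
#' @param embedding An `embedding` object or `n x 2` coordinate matrix.
#' @param grid_resolution Nodes per axis.
#' @return A `decision_surface`: `x`, `y` (axis node vectors) and `labels`
#'   (a `grid_resolution x grid_resolution` character matrix, x indexing
#'   rows).
#' @export
decision_surface <- function(model, embedding, grid_resolution = 200L) {
  if (!inherits(model, "gait_classifier")) {
    stopf("decision_surface needs a fitted gait_classifier")
  }
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates
            else as.matrix(embedding)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  mx <- 0.05 * diff(rx); my <- 0.05 * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = grid_resolution)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = grid_resolution)
  nodes <- as.matrix(expand.grid(f1 = gx, f2 = gy))
  lab <- predict_classifier(model, nodes)
  structure(list(x = gx, y = gy,
                 labels = matrix(as.character(lab), grid_resolution,
                                 grid_resolution)),
            class = "decision_surface")
}

#' @export
plot.decision_surface <- function(x, ...) {
  z <- matrix(as.integer(factor(x$labels)), length(x$x), length(x$y))
  graphics::image(x$x, x$y, z, col = c("#74add1", "#f46d43"),
                  xlab = "dim1", ylab = "dim2", ...)
  invisible(x)
}
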