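# Class balancing on feature tables. All methods return the table with equal
# class counts and a per-row provenance flag; original rows are always kept
# verbatim by the oversamplers. Balancing is meant for training folds only;
# the evaluation pipeline enforces that.

balance_result <- function(df, provenance, method) {
  df$provenance <- provenance
  attr(df, "balancing_method") <- method
  df
}

label_split <- function(table, label_col = "label") {
  if (!label_col %in% names(table)) stopf("no '%s' column", label_col)
  counts <- table(table[[label_col]])
  if (length(counts) != 2L) stopf("balancing expects exactly 2 classes, got %d",
                                  length(counts))
  list(minority = names(counts)[which.min(counts)],
       majority = names(counts)[which.max(counts)],
       n_min = min(counts), n_maj = max(counts))
}

#' Subsample the majority class
#'
#' Majority-class rows are sampled without replacement down to the minority
#' count.
#'
#' @param table Feature data frame with a `label` column.
#' @param seed Integer seed.
#' @return Balanced data frame with a `provenance` column (all `original`).
#' @export
subsample_majority <- function(table, seed = 1L) {
  ls <- label_split(table)
  if (ls$n_min == ls$n_maj) {
    return(balance_result(table, rep("original", nrow(table)), "subsample"))
  }
  maj_idx <- which(table$label == ls$majority)
  keep <- with_seed(seed, sort(sample(maj_idx, ls$n_min)))
  out <- table[sort(c(which(table$label == ls$minority), keep)), ,
               drop = FALSE]
  rownames(out) <- NULL
  balance_result(out, rep("original", nrow(out)), "subsample")
}

#' Oversample the minority class by duplication
#'
#' Minority rows are sampled with replacement until the classes match; the
#' duplicates are flagged.
#'
#' @inheritParams subsample_majority
#' @return Balanced data frame; added rows flagged `duplicated`.
#' @export
oversample_minority <- function(table, seed = 1L) {
  ls <- label_split(table)
  if (ls$n_min < 1L) stopf("empty minority class")
  if (ls$n_min == ls$n_maj) {
    return(balance_result(table, rep("original", nrow(table)), "oversample"))
  }
  min_idx <- which(table$label == ls$minority)
  extra <- with_seed(seed,
                     sample(min_idx, ls$n_maj - ls$n_min, replace = TRUE))
  out <- rbind(table, table[extra, , drop = FALSE])
  rownames(out) <- NULL
  balance_result(out, c(rep("original", nrow(table)),
                        rep("duplicated", length(extra))), "oversample")
}

#' Oversample the minority class with Gaussian jitter
#'
#' As [oversample_minority()], but each added row's feature values are
#' perturbed by Gaussian noise with per-feature standard deviation
#' `noise_scale` times the feature's (minority-class) standard deviation.
#'
#' @inheritParams subsample_majority
#' @param noise_scale Non-negative noise multiplier; 0 reduces to plain
#'   duplication.
#' @return Balanced data frame; added rows flagged `noise`.
#' @export
oversample_noise <- function(table, noise_scale = 0.05, seed = 1L) {
  if (!is.numeric(noise_scale) || noise_scale < 0) {
    stopf("noise_scale must be >= 0")
  }
  ls <- label_split(table)
  if (ls$n_min < 1L) stopf("empty minority class")
  if (ls$n_min == ls$n_maj) {
    return(balance_result(table, rep("original", nrow(table)), "noise"))
  }
  feats <- intersect(feature_columns(), names(table))
  if (!length(feats)) feats <- names(table)[vapply(table, is.numeric, TRUE)]
  min_rows <- table[table$label == ls$minority, , drop = FALSE]
  sds <- vapply(min_rows[feats], function(col) stats::sd(col), 0)
  sds[!is.finite(sds)] <- 0
  n_new <- ls$n_maj - ls$n_min
  new_rows <- with_seed(seed, {
    idx <- sample(seq_len(nrow(min_rows)), n_new, replace = TRUE)
    rows <- min_rows[idx, , drop = FALSE]
    for (j in seq_along(feats)) {
      rows[[feats[j]]] <- rows[[feats[j]]] +
        rnorm(n_new, 0, noise_scale * sds[j])
    }
    rows
  })
  out <- rbind(table, new_rows)
  rownames(out) <- NULL
  balance_result(out, c(rep("original", nrow(table)),
                        rep("noise", n_new)), "noise")
}

#' Balance classes with SMOTE
#'
#' Synthetic minority oversampling: each synthetic row is
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`, `x` a uniformly drawn
#' minority row and `x_nn` one of its `k_neighbors` nearest minority
#' neighbours under Euclidean distance on the feature columns (which should
#' already be scaled comparably). Classes are equalised; synthetic rows are
#' flagged.
#'
#' @inheritParams subsample_majority
#' @param k_neighbors Number of nearest minority neighbours considered;
#'   must be smaller than the minority count.
#' @return Balanced data frame; added rows flagged `smote`.
#' @export
smote <- function(table, k_neighbors = 5L, seed = 1L) {
  ls <- label_split(table)
  if (ls$n_min <= k_neighbors) {
    stopf("minority count (%d) must exceed k_neighbors (%d); use a smaller k",
          ls$n_min, k_neighbors)
  }
  if (ls$n_min == ls$n_maj) {
    return(balance_result(table, rep("original", nrow(table)), "smote"))
  }
  feats <- intersect(feature_columns(), names(table))
  if (!length(feats)) feats <- names(table)[vapply(table, is.numeric, TRUE)]
  min_rows <- table[table$label == ls$minority, , drop = FALSE]
  x <- as.matrix(min_rows[feats])
  dmat <- as.matrix(stats::dist(x))
  diag(dmat) <- Inf
  nn_raw <- apply(dmat, 1L, function(d) order(d)[seq_len(k_neighbors)])
  nn <- if (k_neighbors == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)
  n_new <- ls$n_maj - ls$n_min
  synth <- with_seed(seed, {
    base_i <- sample(seq_len(nrow(x)), n_new, replace = TRUE)
    nb_j <- nn[cbind(base_i, sample(seq_len(k_neighbors), n_new,
                                    replace = TRUE))]
    u <- runif(n_new)
    x[base_i, , drop = FALSE] +
      u * (x[nb_j, , drop = FALSE] - x[base_i, , drop = FALSE])
  })
  new_rows <- min_rows[rep(1L, n_new), , drop = FALSE]  # metadata template
  for (j in seq_along(feats)) new_rows[[feats[j]]] <- synth[, j]
  if ("participant_id" %in% names(new_rows)) {
    new_rows$participant_id <- "synthetic"
  }
  if ("segment_id" %in% names(new_rows)) new_rows$segment_id <- "synthetic"
  out <- rbind(table, new_rows)
  rownames(out) <- NULL
  balance_result(out, c(rep("original", nrow(table)),
                        rep("smote", n_new)), "smote")
}

#' Dispatch a balancing method by name
#'
#' @param table Feature data frame with a `label` column.
#' @param method One of `"smote"`, `"subsample"`, `"oversample"`, `"noise"`,
#'   `"none"`.
#' @param seed Integer seed.
#' @param ... Passed to the method (e.g. `k_neighbors`, `noise_scale`).
#' @return Balanced data frame with a `provenance` column.
#' @export
balance_classes <- function(table, method = c("smote", "subsample",
                                              "oversample", "noise", "none"),
                            seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
    smote = smote(table, seed = seed, ...),
    subsample = subsample_majority(table, seed = seed),
    oversample = oversample_minority(table, seed = seed),
    noise = oversample_noise(table, seed = seed, ...),
    none = balance_result(table, rep("original", nrow(table)), "none"))
}
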