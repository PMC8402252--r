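# Dimensionality reduction to 2-D for visualisation and classification.
# PCA is centred but not scaled; t-SNE and UMAP go through the established
# Rtsne and uwot implementations with recorded hyperparameters. t-SNE has no
# native out-of-sample transform, so held-out points are placed by a
# distance-weighted average of their nearest training points' embedding
# coordinates (used by the strict, leakage-free evaluation mode).

#' Embed a feature matrix in two dimensions
#'
#' @param x Numeric matrix (rows = segments) or `scaled_features` object.
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param seed Integer seed; embeddings are deterministic given
#'   `(x, method, seed, hyperparameters)`.
#' @param perplexity t-SNE perplexity (reduced automatically when the row
#'   count is too small to support it).
#' @param n_neighbors,min_dist UMAP graph size and minimum embedding
#'   distance.
#' @param ... Ignored; present so hyperparameters can be passed uniformly.
#' @return An `embedding` object: `coordinates` (n x 2), `method`, `seed`,
#'   `hyperparameters`, and an internal model handle supporting
#'   [embed_transform()].
#' @export
reduce_features <- function(x, method = c("pca", "tsne", "umap"), seed = 1L,
                            perplexity = 30, n_neighbors = 15,
                            min_dist = 0.1, ...) {
  method <- match.arg(method)
  m <- if (inherits(x, "scaled_features")) x$matrix else as_feature_matrix(x)
  if (nrow(m) < 10L) stopf("need >= 10 rows to embed, got %d", nrow(m))
  hyper <- switch(method,
    pca = list(),
    tsne = list(perplexity = perplexity),
    umap = list(n_neighbors = n_neighbors, min_dist = min_dist))
  fit <- switch(method,
    pca = fit_pca_2d(m),
    tsne = fit_tsne_2d(m, perplexity, seed),
    umap = fit_umap_2d(m, n_neighbors, min_dist, seed))
  structure(list(coordinates = fit$coordinates, method = method, seed = seed,
                 hyperparameters = hyper, model = fit$model),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %s, %d points, seed %d\n", toupper(x$method),
              nrow(x$coordinates), x$seed))
  invisible(x)
}

fit_pca_2d <- function(m) {
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = 2L)
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("dim1", "dim2")
  list(coordinates = coords, model = list(kind = "pca", fit = pc))
}

# deterministic PCA-seeded initialisation, the convention modern t-SNE/UMAP
# practice recommends for reproducibility
pca_init <- function(m) {
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = 2L)$x[, 1:2]
  s <- stats::sd(pc[, 1])
  if (s > 0) pc <- pc / s * 1e-4
  pc
}

fit_tsne_2d <- function(m, perplexity, seed) {
  perp <- min(perplexity, floor((nrow(m) - 1) / 3))
  if (perp < 2) stopf("too few rows for t-SNE")
  y0 <- pca_init(m)
  fit <- with_seed(seed, {
    Rtsne::Rtsne(m, dims = 2L, perplexity = perp, theta = 0,
                 pca = FALSE, max_iter = 1000L, Y_init = y0,
                 num_threads = 1L, check_duplicates = FALSE)
  })
  coords <- fit$Y
  colnames(coords) <- c("dim1", "dim2")
  list(coordinates = coords,
       model = list(kind = "tsne", train_x = m, train_y = coords))
}

fit_umap_2d <- function(m, n_neighbors, min_dist, seed) {
  nn <- min(n_neighbors, nrow(m) - 1L)
  fit <- uwot::umap(m, n_components = 2L, n_neighbors = nn,
                    min_dist = min_dist, seed = as.integer(seed),
                    n_threads = 1L, n_sgd_threads = 1L, ret_model = TRUE,
                    init = "spca", verbose = FALSE)
  coords <- fit$embedding
  colnames(coords) <- c("dim1", "dim2")
  list(coordinates = coords, model = list(kind = "umap", fit = fit))
}

#' Project new rows into a fitted embedding
#'
#' PCA uses its linear projection; UMAP uses the uwot transform; t-SNE,
#' which defines no parametric map, places each new point at the
#' inverse-distance-weighted average of its `k = 5` nearest training points'
#' embedding coordinates.
#'
#' @param embedding An `embedding` object from [reduce_features()].
#' @param newx Numeric matrix with the same columns as the training data.
#' @return `nrow(newx) x 2` coordinate matrix.
#' @export
embed_transform <- function(embedding, newx) {
  stopifnot(inherits(embedding, "embedding"))
  newx <- as_feature_matrix(newx)
  model <- embedding$model
  coords <- switch(model$kind,
    pca = predict(model$fit, newx)[, 1:2, drop = FALSE],
    umap = uwot::umap_transform(newx, model$fit, n_threads = 1L),
    tsne = knn_barycentric_transform(model$train_x, model$train_y, newx,
                                     k = 5L))
  colnames(coords) <- c("dim1", "dim2")
  coords
}

# inverse-distance-weighted placement among k nearest training points
knn_barycentric_transform <- function(train_x, train_y, newx, k = 5L) {
  k <- min(k, nrow(train_x))
  out <- matrix(0, nrow(newx), 2L)
  for (i in seq_len(nrow(newx))) {
    d <- sqrt(colSums((t(train_x) - newx[i, ])^2))
    nn <- order(d)[seq_len(k)]
    w <- 1 / pmax(d[nn], 1e-12)
    out[i, ] <- colSums(train_y[nn, , drop = FALSE] * w) / sum(w)
  }
  out
}
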