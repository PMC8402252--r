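# Feature scaling with retained per-feature parameters, so parameters fitted
# on training rows can be applied unchanged to held-out rows.

#' Scale a feature matrix
#'
#' Three classical schemes over the columns of a numeric matrix or the
#' feature columns of a feature data frame:
#' \describe{
#'   \item{rescale}{min-max: `(x - min) / (max - min)`, output in `[0, 1]`.}
#'   \item{mean_norm}{`(x - mean) / (max - min)`, output mean 0.}
#'   \item{zscore}{`(x - mean) / sd` with the population standard deviation,
#'     output mean 0 and sd 1.}
#'   \item{none}{identity (parameters still recorded).}
#' }
#' Zero-range (or zero-sd) columns are mapped to all zeros with a warning.
#'
#' @param x Numeric matrix or feature data frame (from [cohort_features()]).
#' @param method One of `"zscore"`, `"rescale"`, `"mean_norm"`, `"none"`.
#' @return A `scaled_features` object: `matrix` (scaled values), `method`,
#'   and the per-feature `parameters` needed to transform new data.
#' @examples
#' sf <- scale_features(matrix(c(2, 4, 6), 3, 1), "rescale")
#' sf$matrix
#' @export
scale_features <- function(x, method = c("zscore", "rescale", "mean_norm",
                                         "none")) {
  method <- match.arg(method)
  m <- as_feature_matrix(x)
  ctr <- switch(method,
    rescale = apply(m, 2, min),
    mean_norm = colMeans(m),
    zscore = colMeans(m),
    none = rep(0, ncol(m)))
  scl <- switch(method,
    rescale = apply(m, 2, max) - apply(m, 2, min),
    mean_norm = apply(m, 2, max) - apply(m, 2, min),
    zscore = apply(m, 2, function(col) sqrt(mean((col - mean(col))^2))),
    none = rep(1, ncol(m)))
  degenerate <- scl <= 0
  if (any(degenerate)) {
    warning(sprintf("zero-range feature(s) set to 0: %s",
                    paste(colnames(m)[degenerate], collapse = ", ")),
            call. = FALSE)
    scl[degenerate] <- 1
    ctr[degenerate] <- if (method == "rescale") {
      apply(m, 2, min)[degenerate]
    } else ctr[degenerate]
  }
  params <- list(center = ctr, scale = scl, degenerate = degenerate)
  structure(list(matrix = apply_scaling(params, m), method = method,
                 parameters = params),
            class = "scaled_features")
}

#' Apply stored scaling parameters to new data
#'
#' @param params The `parameters` element of a `scaled_features` object (or
#'   the object itself).
#' @param x Numeric matrix or feature data frame with the same columns.
#' @return Scaled numeric matrix.
#' @export
apply_scaling <- function(params, x) {
  if (inherits(params, "scaled_features")) params <- params$parameters
  m <- as_feature_matrix(x)
  out <- sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
  out[, params$degenerate] <- 0
  out
}

#' @rdname scale_features
#' @export
rescale_minmax <- function(x) scale_features(x, "rescale")

#' @rdname scale_features
#' @export
mean_normalize <- function(x) scale_features(x, "mean_norm")

#' @rdname scale_features
#' @export
standardize <- function(x) scale_features(x, "zscore")

# coerce a feature data frame (or numeric matrix) to the numeric matrix of
# feature columns
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    return(x)
  }
  if (is.data.frame(x)) {
    cols <- intersect(feature_columns(), names(x))
    if (!length(cols)) cols <- names(x)[vapply(x, is.numeric, TRUE)]
    m <- as.matrix(x[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    return(m)
  }
  stopf("expected a numeric matrix or feature data frame")
}
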