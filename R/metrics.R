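# Confusion-matrix metrics and the severity-separation report.

#' Confusion-matrix metrics
#'
#' Counts and proportions for binary classification. Sensitivity is recall
#' on the positive (ataxic) class, specificity recall on the negative
#' (healthy) class.
#'
#' @param truths,predictions Equal-length label vectors.
#' @param positive_class The positive label (default `"ataxic"`).
#' @return A `confusion_metrics` list: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`. With no positive-class truths,
#'   sensitivity is `NA` with a warning (and symmetrically for specificity).
#' @examples
#' confusion_metrics(c("a", "a", "h"), c("a", "h", "h"), positive_class = "a")
#' @export
confusion_metrics <- function(truths, predictions, positive_class = "ataxic") {
  if (length(truths) == 0L) stopf("empty input")
  if (length(truths) != length(predictions)) {
    stopf("truths and predictions differ in length")
  }
  truths <- as.character(truths); predictions <- as.character(predictions)
  pos_t <- truths == positive_class
  pos_p <- predictions == positive_class
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  sens <- if (tp + fn == 0) {
    warning("no positive-class truths: sensitivity undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative-class truths: specificity undefined", call. = FALSE)
    NA_real_
  } else tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(truths),
                 sensitivity = sens, specificity = spec),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f  sensitivity %.3f  specificity %.3f  (tp %d fp %d tn %d fn %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Severity separation of an embedding
#'
#' Quantifies how well a 2-D embedding orders segments by clinical severity:
#' the rank (Spearman) correlation between severity and the projection of
#' the embedding onto its severity-discriminant direction (the least-squares
#' direction for severity in embedding space), and the ratio of mean
#' between-severity-tertile to mean within-tertile pairwise distance.
#'
#' @param embedding An `embedding` object or an `n x 2` coordinate matrix.
#' @param severities One severity value per embedded segment; at least three
#'   distinct values required.
#' @param group Optional grouping vector (e.g. participant id); when given,
#'   coordinates and severities are first averaged per group so the
#'   statistics describe subject-level separation.
#' @return A `severity_report`: `rank_correlation`, `distance_ratio`,
#'   `coordinates`, `severities`.
#' @export
severity_report <- function(embedding, severities, group = NULL) {
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates
            else as.matrix(embedding)
  if (nrow(coords) != length(severities)) {
    stopf("one severity per embedded segment required")
  }
  if (!is.null(group)) {
    coords <- cbind(
      tapply(coords[, 1], group, mean)[unique(as.character(group))],
      tapply(coords[, 2], group, mean)[unique(as.character(group))])
    severities <- as.numeric(
      tapply(severities, group, mean)[unique(as.character(group))])
  }
  if (length(unique(severities)) < 3L) {
    stopf("no severity variation: need >= 3 distinct severities")
  }
  fit <- stats::lm.fit(cbind(1, coords), severities)
  w <- fit$coefficients[-1]
  w[!is.finite(w)] <- 0  # collinear axes drop out of the direction
  if (sqrt(sum(w^2)) == 0) {
    stopf("degenerate embedding: no discriminant direction")
  }
  w <- w / sqrt(sum(w^2))
  proj <- coords %*% w
  rho <- stats::cor(severities, proj, method = "spearman")[1]
  tert <- cut(rank(severities, ties.method = "first"),
              breaks = 3, labels = FALSE)
  d <- as.matrix(stats::dist(coords))
  same <- outer(tert, tert, "==")
  ut <- upper.tri(d)
  within <- mean(d[ut & same])
  between <- mean(d[ut & !same])
  structure(list(rank_correlation = as.numeric(rho),
                 distance_ratio = between / within,
                 coordinates = coords, severities = severities),
            class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf(
    "<severity_report> rank correlation %.3f, tertile distance ratio %.3f (n = %d)\n",
    x$rank_correlation, x$distance_ratio, nrow(x$coordinates)))
  invisible(x)
}
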