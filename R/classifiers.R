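# The ten shallow classifiers of the evaluation grid, behind a uniform
# fit/predict registry. Stochastic learners are made reproducible by seeding
# their fits. AdaBoost (discrete SAMME over depth-1 rpart stumps) is
# implemented here directly.

#' Names of the registered classifiers
#'
#' The ten classifiers of the evaluation grid. `include_quadratic = TRUE`
#' additionally registers a quadratic discriminant classifier (requires
#' MASS), which is not part of the default grid.
#'
#' @param include_quadratic Add `"Quadratic"` to the registry.
#' @return Character vector of registry names.
#' @export
classifier_names <- function(include_quadratic = FALSE) {
  n <- c("Logistic Regression", "Linear SVM", "Poly SVM", "RBF SVM",
         "Naive Bayes", "Nearest Neighbors", "Decision Tree",
         "Random Forest", "Neural Net", "AdaBoost")
  if (include_quadratic) n <- c(n, "Quadratic")
  n
}

default_hyperparameters <- function() {
  list(knn_k = 5L, svm_poly_degree = 3L, rf_ntree = 100L,
       nnet_size = 100L, nnet_decay = 0.01, nnet_maxit = 300L,
       ada_rounds = 50L)
}

#' Fit a registered classifier
#'
#' @param name A name from [classifier_names()] (error lists the registry
#'   for unknown names).
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (coerced to factor).
#' @param seed Integer seed controlling any stochastic element of the fit.
#' @param hyper Named list of hyperparameter overrides (`knn_k`,
#'   `svm_poly_degree`, `rf_ntree`, `nnet_size`, `nnet_decay`, `nnet_maxit`,
#'   `ada_rounds`).
#' @return A `gait_classifier` object usable with [predict_classifier()].
#' @export
fit_classifier <- function(name, x, y, seed = 1L, hyper = list()) {
  registry <- classifier_names(include_quadratic = TRUE)
  if (!name %in% registry) {
    stopf("unknown classifier '%s'; registry: %s", name,
          paste(registry, collapse = ", "))
  }
  hp <- utils::modifyList(default_hyperparameters(), hyper)
  x <- as.matrix(x); storage.mode(x) <- "double"
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    # degenerate single-class training: constant classifier
    return(structure(list(name = name, constant = levels(y)[1],
                          levels = levels(y)),
                     class = "gait_classifier"))
  }
  df <- data.frame(y = y, x)
  fml <- stats::as.formula(paste("y ~", paste(colnames(x), collapse = " + ")))
  environment(fml) <- environment()
  fit <- with_seed(seed, switch(name,
    "Logistic Regression" = glm(fml, data = df, family = binomial()),
    "Linear SVM" = e1071::svm(fml, data = df, kernel = "linear"),
    "Poly SVM" = e1071::svm(fml, data = df, kernel = "polynomial",
                            degree = hp$svm_poly_degree),
    "RBF SVM" = e1071::svm(fml, data = df, kernel = "radial"),
    "Naive Bayes" = e1071::naiveBayes(fml, data = df),
    "Nearest Neighbors" = list(train_x = x, train_y = y, k = hp$knn_k),
    "Decision Tree" = rpart::rpart(fml, data = df, method = "class"),
    "Random Forest" = randomForest::randomForest(x, y,
                                                 ntree = hp$rf_ntree),
    "Neural Net" = nnet::nnet(fml, data = df, size = hp$nnet_size,
                              decay = hp$nnet_decay, maxit = hp$nnet_maxit,
                              trace = FALSE, MaxNWts = 10000L),
    "AdaBoost" = fit_adaboost(x, y, rounds = hp$ada_rounds),
    "Quadratic" = MASS::qda(x, grouping = y)
  ))
  structure(list(name = name, fit = fit, levels = levels(y), seed = seed),
            class = "gait_classifier")
}

#' Predict with a fitted registry classifier
#'
#' @param model A `gait_classifier` from [fit_classifier()].
#' @param newx Numeric matrix with the training columns.
#' @return Factor of predicted labels (training levels).
#' @export
predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "gait_classifier"))
  newx <- as.matrix(newx); storage.mode(newx) <- "double"
  colnames(newx) <- paste0("f", seq_len(ncol(newx)))
  if (!is.null(model$constant)) {
    return(factor(rep(model$constant, nrow(newx)), levels = model$levels))
  }
  nd <- as.data.frame(newx)
  fit <- model$fit
  pred <- switch(model$name,
    "Logistic Regression" = {
      p <- predict(fit, newdata = nd, type = "response")
      factor(model$levels[1L + (p > 0.5)], levels = model$levels)
    },
    "Linear SVM" = predict(fit, newdata = nd),
    "Poly SVM" = predict(fit, newdata = nd),
    "RBF SVM" = predict(fit, newdata = nd),
    "Naive Bayes" = predict(fit, newdata = nd),
    "Nearest Neighbors" = with_seed(model$seed %||% 1L, {
      class::knn(fit$train_x, newx, fit$train_y, k = min(fit$k,
                                                         nrow(fit$train_x)))
    }),
    "Decision Tree" = predict(fit, newdata = nd, type = "class"),
    "Random Forest" = predict(fit, newdata = newx),
    "Neural Net" = {
      p <- predict(fit, newdata = nd, type = "raw")
      factor(model$levels[1L + (p[, 1] > 0.5)], levels = model$levels)
    },
    "AdaBoost" = predict_adaboost(fit, newx),
    "Quadratic" = predict(fit, newdata = newx)$class
  )
  factor(as.character(pred), levels = model$levels)
}

#' Fit, then predict, one registered classifier
#'
#' One-call convenience: train on `(train_x, train_y)`, return one predicted
#' label per row of `test_x`. Deterministic under `seed` for stochastic
#' learners.
#'
#' @param name Classifier name from [classifier_names()].
#' @param train_x,train_y Training features and labels.
#' @param test_x Test feature matrix.
#' @param seed Integer seed.
#' @param hyper Hyperparameter overrides.
#' @return Factor of predictions.
#' @export
fit_predict <- function(name, train_x, train_y, test_x, seed = 1L,
                        hyper = list()) {
  model <- fit_classifier(name, train_x, train_y, seed = seed, hyper = hyper)
  predict_classifier(model, test_x)
}

# ---- discrete AdaBoost (SAMME) over depth-1 rpart stumps -------------------

fit_adaboost <- function(x, y, rounds = 50L) {
  n <- nrow(x)
  df <- data.frame(y = y, x)
  fml <- stats::as.formula(paste("y ~", paste(colnames(x), collapse = " + ")))
  environment(fml) <- environment()
  ctrl <- rpart::rpart.control(maxdepth = 1L, minsplit = 2L, cp = 0,
                               xval = 0L)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(rounds)) {
    wv <- w * n  # rpart prefers weights on the count scale
    stump <- rpart::rpart(fml, data = df, weights = wv, method = "class",
                          control = ctrl)
    pred <- predict(stump, newdata = df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) break
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, newx) {
  nd <- as.data.frame(newx)
  if (!length(fit$stumps)) {
    return(factor(rep(fit$levels[1], nrow(newx)), levels = fit$levels))
  }
  score <- numeric(nrow(newx))
  for (t in seq_along(fit$stumps)) {
    p <- predict(fit$stumps[[t]], newdata = nd, type = "class")
    score <- score + fit$alphas[t] * ifelse(p == fit$levels[2], 1, -1)
  }
  factor(fit$levels[1L + (score > 0)], levels = fit$levels)
}
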