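test_that("PCA embedding is exact for rank-2 data and matches an SVD oracle", {
  base <- ataxgait:::with_seed(3, {
    u <- matrix(rnorm(40 * 2), 40, 2)
    dirs <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
    u %*% t(dirs)
  })
  emb <- reduce_features(base, "pca")
  # plane-embedded data: the two components reconstruct all variance
  centred <- scale(base, center = TRUE, scale = FALSE)
  expect_equal(sum(emb$coordinates^2), sum(centred^2), tolerance = 1e-9)

  # independent oracle: coordinates from a direct SVD, up to per-axis sign
  sv <- svd(centred)
  oracle <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(emb$coordinates[, j], oracle[, j],
                                 tolerance = 1e-8)) ||
                isTRUE(all.equal(emb$coordinates[, j], -oracle[, j],
                                 tolerance = 1e-8)))
  }
})

test_that("all three reducers preserve separation of distant blobs", {
  bd <- blob_data(n_per = 30, separation = 10)
  for (method in c("pca", "tsne", "umap")) {
    emb <- reduce_features(bd$x, method, seed = 8L)
    expect_true(all(is.finite(emb$coordinates)))
    expect_equal(nrow(emb$coordinates), nrow(bd$x))
    # leave-one-out 1-NN on the embedding classifies perfectly
    d <- as.matrix(dist(emb$coordinates))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    expect_equal(mean(bd$y[nn] == bd$y), 1.0)
  }
  expect_error(reduce_features(bd$x, "lda"), "arg")
})

test_that("embeddings are deterministic under a fixed seed", {
  bd <- blob_data(n_per = 20, separation = 6, seed = 9)
  for (method in c("pca", "tsne", "umap")) {
    e1 <- reduce_features(bd$x, method, seed = 4L)
    e2 <- reduce_features(bd$x, method, seed = 4L)
    expect_identical(e1$coordinates, e2$coordinates)
  }
})

test_that("out-of-sample transform places new points near their class", {
  bd <- blob_data(n_per = 25, separation = 10, seed = 10)
  new_bd <- blob_data(n_per = 5, separation = 10, seed = 11)
  for (method in c("pca", "tsne", "umap")) {
    emb <- reduce_features(bd$x, method, seed = 2L)
    proj <- embed_transform(emb, new_bd$x)
    expect_equal(dim(proj), c(10L, 2L))
    pred <- fit_predict("Nearest Neighbors", emb$coordinates, bd$y, proj,
                        seed = 3L, hyper = list(knn_k = 3L))
    expect_equal(mean(pred == new_bd$y), 1.0)
  }
})

test_that("holdout splits are stratified 60/40", {
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(55, 45)),
                    participant_id = sprintf("P%02d", rep(1:20, 5)))
  folds <- cv_split(tab, cv_scheme("holdout_60_40", seed = 6L))
  expect_length(folds, 1L)
  expect_equal(length(folds[[1]]$train), 60L)
  expect_equal(length(folds[[1]]$test), 40L)
  tr <- table(tab$label[folds[[1]]$train])
  expect_lte(abs(tr[["healthy"]] - 33), 1)
  expect_lte(abs(tr[["ataxic"]] - 27), 1)
  expect_length(intersect(folds[[1]]$train, folds[[1]]$test), 0L)
})

test_that("leave-one-group-out never splits a participant", {
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(50, 50)),
                    participant_id = sprintf("P%02d", rep(1:10, each = 10)))
  folds <- cv_split(tab, cv_scheme("leave_one_group_out"))
  expect_length(folds, 10L)
  for (f in folds) {
    expect_length(intersect(tab$participant_id[f$train],
                            tab$participant_id[f$test]), 0L)
    expect_equal(length(unique(tab$participant_id[f$test])), 1L)
  }
  one <- tab[tab$participant_id == "P01", ]
  expect_error(cv_split(one, cv_scheme("leave_one_group_out")), ">= 2")
})

test_that("classifier registry fits, predicts and memorises", {
  bd <- blob_data(n_per = 20, separation = 10, seed = 12)
  emb <- reduce_features(bd$x, "pca")$coordinates
  for (name in classifier_names()) {
    pred <- suppressWarnings(fit_predict(name, emb, bd$y, emb, seed = 5L))
    expect_length(pred, nrow(emb))
    expect_gte(mean(pred == bd$y), 0.95)  # separable training data
  }
  # exact memorisation for 1-NN
  p1 <- fit_predict("Nearest Neighbors", emb, bd$y, emb, seed = 5L,
                    hyper = list(knn_k = 1L))
  expect_equal(mean(p1 == bd$y), 1.0)
  # degenerate single-class training: constant predictions
  const <- fit_predict("Random Forest", emb[1:10, ],
                       rep("healthy", 10), emb, seed = 5L)
  expect_true(all(const == "healthy"))
  expect_error(fit_predict("Perceptron", emb, bd$y, emb), "registry")
})

test_that("random forest separates distant blobs near-perfectly", {
  bd <- blob_data(n_per = 100, separation = 10, seed = 13)
  idx <- ataxgait:::with_seed(2, sample(200, 120))
  pred <- fit_predict("Random Forest", bd$x[idx, ], bd$y[idx],
                      bd$x[-idx, ], seed = 6L)
  expect_gte(mean(pred == bd$y[-idx]), 0.99)
})

test_that("stochastic classifiers are reproducible under a seed", {
  bd <- blob_data(n_per = 40, separation = 2, seed = 14)  # overlapping
  for (name in c("Random Forest", "Neural Net", "Nearest Neighbors")) {
    p1 <- suppressWarnings(fit_predict(name, bd$x[1:60, ], bd$y[1:60],
                                       bd$x[61:80, ], seed = 9L))
    p2 <- suppressWarnings(fit_predict(name, bd$x[1:60, ], bd$y[1:60],
                                       bd$x[61:80, ], seed = 9L))
    expect_identical(p1, p2)
  }
})

test_that("the evaluation grid has full structure and valid metrics", {
  ft <- fix_features()
  g <- suppressWarnings(suppressMessages(
    evaluate_grid(ft, seed = 19L,
                  scheme = cv_scheme("holdout_60_40", seed = 19L))))
  expect_s3_class(g, "gait_grid")
  expect_equal(nrow(g$cells), 30L)
  expect_true(all(is.na(g$cells$error)))
  m <- g$cells[, c("accuracy", "sensitivity", "specificity")]
  expect_true(all(m >= 0 & m <= 1))
  am <- accuracy_matrix(g)
  expect_equal(dim(am), c(10L, 3L))

  g2 <- suppressWarnings(suppressMessages(
    evaluate_grid(ft, seed = 19L,
                  scheme = cv_scheme("holdout_60_40", seed = 19L))))
  expect_identical(g$cells, g2$cells)  # full-grid determinism
})

test_that("strict mode fits scaling and reducers on training rows only", {
  ft <- fix_features()
  g <- suppressWarnings(
    evaluate_grid(ft, reducers = c("pca", "tsne"),
                  classifiers = c("Random Forest", "Nearest Neighbors"),
                  seed = 23L, scheme = cv_scheme("holdout_60_40", seed = 23L),
                  mode = "strict", balancing = "none"))
  expect_true(all(is.na(g$cells$error)))
  expect_true(all(g$cells$accuracy >= 0 & g$cells$accuracy <= 1))
  expect_true(is.na(g$provenance$leakage_warning))
  # leakage guard: training-only scaling parameters differ from global ones
  fold <- cv_split(ft, cv_scheme("holdout_60_40", seed = 23L))[[1]]
  tr_scale <- scale_features(ft[fold$train, ], "zscore")
  all_scale <- scale_features(ft, "zscore")
  expect_false(isTRUE(all.equal(tr_scale$parameters$center,
                                all_scale$parameters$center)))
})

test_that("decision surfaces reflect the trained classifier", {
  bd <- blob_data(n_per = 25, separation = 8, seed = 15)
  emb <- reduce_features(bd$x, "pca")$coordinates
  svm <- fit_classifier("Linear SVM", emb, bd$y, seed = 2L)
  surf <- decision_surface(svm, emb, grid_resolution = 200L)
  expect_equal(dim(surf$labels), c(200L, 200L))
  # boundary nodes of a linear SVM lie on a straight band: collect label
  # flips along both axes and check collinearity via PCA
  lab <- surf$labels
  pts <- NULL
  for (i in 1:200) {
    flip <- which(lab[i, -1] != lab[i, -200])
    if (length(flip)) {
      pts <- rbind(pts, cbind(surf$x[i], (surf$y[flip] +
                                            surf$y[flip + 1]) / 2))
    }
    flip <- which(lab[-1, i] != lab[-200, i])
    if (length(flip)) {
      pts <- rbind(pts, cbind((surf$x[flip] + surf$x[flip + 1]) / 2,
                              surf$y[i]))
    }
  }
  expect_gt(nrow(pts), 50)
  ev <- prcomp(pts)$sdev^2
  expect_gt(ev[1] / sum(ev), 0.99)

  # 1-NN surface memorises each training point's cell
  nn1 <- fit_classifier("Nearest Neighbors", emb, bd$y, seed = 2L,
                        hyper = list(knn_k = 1L))
  surf1 <- decision_surface(nn1, emb, grid_resolution = 120L)
  for (i in seq_len(nrow(emb))) {
    xi <- which.min(abs(surf1$x - emb[i, 1]))
    yi <- which.min(abs(surf1$y - emb[i, 2]))
    expect_equal(surf1$labels[xi, yi], as.character(bd$y[i]))
  }
  expect_error(decision_surface(list(), emb), "gait_classifier")
})
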