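test_that("min-max rescaling maps columns onto [0, 1]", {
  m <- cbind(a = c(2, 4, 6), b = c(0, 0.5, 1))
  sf <- rescale_minmax(m)
  expect_equal(sf$matrix[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(sf$matrix[, "b"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_true(all(sf$matrix >= 0 & sf$matrix <= 1))
  expect_warning(out <- rescale_minmax(cbind(k = c(3, 3, 3))), "zero-range")
  expect_equal(unname(out$matrix[, 1]), c(0, 0, 0))
})

test_that("mean normalisation centres columns and keeps symmetry", {
  sf <- mean_normalize(cbind(a = c(2, 4, 6)))
  expect_equal(unname(sf$matrix[, 1]), c(-0.5, 0, 0.5))
  sym <- cbind(s = c(-3, -1, 1, 3))
  out <- mean_normalize(sym)$matrix[, 1]
  expect_equal(unname(out), -rev(unname(out)))
  expect_lt(abs(mean(mean_normalize(cbind(r = rnorm(50)))$matrix)), 1e-12)
})

test_that("z-score standardisation yields population mean 0 and sd 1", {
  sf <- standardize(cbind(a = c(2, 4, 6)))
  expect_equal(unname(sf$matrix[, 1]), c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  x <- cbind(v = c(1.5, -2, 0.3, 4, 2.2))
  z <- standardize(x)$matrix[, 1]
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)
  # affine invariance: a * x + b standardises to the same values
  z2 <- standardize(cbind(v = 3.2 * x[, 1] + 7))$matrix[, 1]
  expect_equal(z, z2, tolerance = 1e-12)
})

test_that("stored scaling parameters reproduce and transfer", {
  m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (meth in c("rescale", "mean_norm", "zscore", "none")) {
    sf <- scale_features(m, meth)
    expect_equal(apply_scaling(sf, m), sf$matrix, tolerance = 1e-12)
  }
})

test_that("majority subsampling equalises counts deterministically", {
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(30, 20)),
                    f = seq_len(50))
  out <- subsample_majority(tab, seed = 3L)
  expect_equal(unname(table(out$label)), c(20L, 20L), ignore_attr = TRUE)
  expect_true(all(out$provenance == "original"))
  expect_identical(subsample_majority(tab, seed = 3L), out)
  bal <- tab[c(1:20, 31:50), ]
  expect_equal(nrow(subsample_majority(bal, seed = 1L)), 40L)
})

test_that("minority oversampling duplicates only existing rows", {
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(30, 20)),
                    f = seq_len(50))
  out <- oversample_minority(tab, seed = 5L)
  expect_equal(unname(table(out$label)), c(30L, 30L), ignore_attr = TRUE)
  dup <- out[out$provenance == "duplicated", ]
  expect_equal(nrow(dup), 10L)
  expect_true(all(dup$f %in% tab$f[tab$label == "ataxic"]))
})

test_that("noise oversampling perturbs at the configured scale", {
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(30, 20)),
                    cadence = c(rnorm(30, 100), rnorm(20, 90)))
  out0 <- oversample_noise(tab, noise_scale = 0, seed = 9L)
  ref <- oversample_minority(tab, seed = 9L)
  expect_equal(out0$cadence, ref$cadence)
  out <- oversample_noise(tab, noise_scale = 0.1, seed = 9L)
  added <- out$cadence[out$provenance == "noise"]
  expect_false(any(added %in% tab$cadence))
  expect_error(oversample_noise(tab, noise_scale = -1), ">= 0")

  # Monte-Carlo: perturbation sd matches noise_scale * column sd. With the
  # same seed, plain duplication resamples the identical rows, so the
  # element-wise difference isolates the injected noise.
  big <- data.frame(label = rep(c("healthy", "ataxic"), c(10100, 100)),
                    cadence = ataxgait:::with_seed(1, rnorm(10200, 100, 5)))
  outb <- oversample_noise(big, noise_scale = 0.5, seed = 2L)
  refb <- oversample_minority(big, seed = 2L)
  pert <- outb$cadence[outb$provenance == "noise"] -
    refb$cadence[refb$provenance == "duplicated"]
  base_sd <- stats::sd(big$cadence[big$label == "ataxic"])
  expect_equal(stats::sd(pert), 0.5 * base_sd, tolerance = 0.05)
})

test_that("SMOTE interpolates inside the minority geometry", {
  # two minority points: every synthetic sample lies on their segment
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(10, 2)),
                    f1 = c(rnorm(10, 5), 0, 1),
                    f2 = c(rnorm(10, 5), 0, 2))
  out <- smote(tab, k_neighbors = 1L, seed = 4L)
  syn <- out[out$provenance == "smote", ]
  expect_equal(nrow(syn), 8L)
  # on the segment (0,0)-(1,2): f2 = 2 * f1, 0 <= f1 <= 1
  expect_true(all(abs(syn$f2 - 2 * syn$f1) < 1e-12))
  expect_true(all(syn$f1 >= 0 & syn$f1 <= 1))

  # synthetic points stay inside the minority bounding box
  tab2 <- data.frame(label = rep(c("healthy", "ataxic"), c(60, 20)),
                     f1 = c(rnorm(60, 10), runif(20)),
                     f2 = c(rnorm(60, 10), runif(20, -1, 1)))
  out2 <- smote(tab2, seed = 6L)
  syn2 <- out2[out2$provenance == "smote", ]
  minr <- tab2[tab2$label == "ataxic", ]
  expect_true(all(syn2$f1 >= min(minr$f1) & syn2$f1 <= max(minr$f1)))
  expect_true(all(syn2$f2 >= min(minr$f2) & syn2$f2 <= max(minr$f2)))

  expect_error(smote(tab, k_neighbors = 2L), "smaller k")
})

test_that("SMOTE interpolation weights are uniform", {
  # minority at {0, 1} in 1-D: synthetic values ~ Uniform(0, 1)
  n_syn <- 2000L
  tab <- data.frame(label = rep(c("healthy", "ataxic"), c(n_syn + 2L, 2L)),
                    f1 = c(rnorm(n_syn + 2L, 10), 0, 1))
  out <- smote(tab, k_neighbors = 1L, seed = 13L)
  syn <- out$f1[out$provenance == "smote"]
  expect_equal(length(syn), n_syn)
  ks <- suppressWarnings(stats::ks.test(syn, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("every balancing method equalises the class counts", {
  ft <- fix_features()
  for (meth in c("smote", "subsample", "oversample", "noise")) {
    out <- balance_classes(ft, meth, seed = 11L)
    expect_equal(length(unique(table(out$label))), 1L)
    orig <- out[out$provenance == "original", ]
    expect_equal(nrow(orig), if (meth == "subsample") nrow(out) else nrow(ft))
  }
})
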