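test_that("noise-free generation yields exactly the drawn step geometry", {
  p <- short_params(step_length_sd = 0, tremor_amplitude = 0,
                    sway_amplitude = 0)
  gt <- generate_recording(p, "P01", seed = 3L)
  expect_true(all(abs(gt$truth$per_step_lengths - p$step_length_mean) < 1e-12))
  # adjacent-contact distances reproduce the drawn step lengths exactly
  ct <- gt$truth$contacts
  st <- gt$truth$steps
  d <- vapply(seq_len(nrow(st)), function(i) {
    a <- unlist(ct[st$stance_contact[i], c("x", "y", "z")])
    b <- unlist(ct[st$landing_contact[i], c("x", "y", "z")])
    sqrt(sum((b - a)^2))
  }, 0)
  expect_true(all(abs(d - st$length) < 1e-9))
})

test_that("ground-truth step geometry holds for noisy draws and two passes", {
  gt <- generate_recording(gait_params(step_length_sd = 0.05), "P02",
                           seed = 9L)
  ct <- gt$truth$contacts
  st <- gt$truth$steps
  d <- vapply(seq_len(nrow(st)), function(i) {
    a <- unlist(ct[st$stance_contact[i], c("x", "y", "z")])
    b <- unlist(ct[st$landing_contact[i], c("x", "y", "z")])
    sqrt(sum((b - a)^2))
  }, 0)
  expect_true(all(abs(d - st$length) < 1e-9))
  expect_equal(nrow(gt$truth$turn_intervals), 1L)
  iv <- gt$truth$turn_intervals
  expect_true(iv$start > 1 && iv$end <= gt$recording$n_samples)
})

test_that("ground-truth contacts imply the configured normal-range cadence", {
  gt <- generate_recording(gait_params(cadence = 110), "P03", seed = 1L)
  ct <- gt$truth$contacts
  ct <- ct[!ct$in_turn & ct$pass == 1, ]
  ct <- ct[order(ct$sample), ]
  cad <- (nrow(ct) - 1) /
    ((ct$sample[nrow(ct)] - ct$sample[1]) / gt$recording$sampling_rate) * 60
  expect_gt(cad, 100)
  expect_lt(cad, 115)
})

test_that("generation is bit-identical under identical params and seed", {
  p <- short_params()
  a <- generate_recording(p, "P04", seed = 77L)
  b <- generate_recording(p, "P04", seed = 77L)
  expect_identical(a, b)
  c <- generate_recording(p, "P04", seed = 78L)
  expect_false(identical(a$recording$joints$pelvis,
                         c$recording$joints$pelvis))
})

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(gait_params(cadence = -1), "cadence")
  expect_error(gait_params(sampling_rate = 90), "sampling_rate")
  expect_error(gait_params(tremor_band = c(20, 35)), "tremor_band")
  expect_error(gait_params(step_length_sd = -0.1), "step_length_sd")
  expect_error(generate_recording(gait_params(step_length_mean = 0.2)),
               "step_length_mean")
})

test_that("cohorts have the configured size, labels and derived seeds", {
  coh <- generate_cohort(4, 5, c(0.25, 1), short_params(), seed = 31L)
  expect_length(coh, 9L)
  labels <- vapply(coh, function(r) r$recording$label, "")
  expect_equal(sum(labels == "ataxic"), 5L)
  expect_equal(sum(labels == "healthy"), 4L)
  sev <- vapply(coh, function(r) r$recording$severity, 0)
  expect_true(all(sev[labels == "healthy"] == 0))
  expect_true(all(sev[labels == "ataxic"] >= 0.25 &
                    sev[labels == "ataxic"] <= 1))
  coh2 <- generate_cohort(4, 5, c(0.25, 1), short_params(), seed = 31L)
  expect_identical(coh, coh2)
  expect_error(generate_cohort(0, 0), "participant")
})

test_that("identity effect sizes make ataxic and healthy indistinguishable", {
  es0 <- effect_sizes(sway = 0, step_sd = 0, tremor = 0, cadence = 0)
  # between-subject jitter off: the null case compares identical populations
  cv0 <- c(cadence = 0, step_length = 0, step_height = 0, sway = 0,
           step_sd = 0, tremor = 0)
  coh <- generate_cohort(6, 6, c(0.5, 1), short_params(), es0, seed = 41L,
                         subject_cv = cv0)
  ft <- suppressWarnings(cohort_features(coh, max_contacts = 12L))
  for (f in c("com_std", "cadence", "energy_high")) {
    pv <- suppressWarnings(
      stats::wilcox.test(ft[[f]][ft$label == "healthy"],
                         ft[[f]][ft$label == "ataxic"])$p.value)
    expect_gt(pv, 0.01)
  }
})

test_that("severity monotonically shifts the coupled parameters", {
  p <- gait_params()
  es <- effect_sizes()
  sev <- c(0, 0.25, 0.5, 0.75, 1)
  shifted <- lapply(sev, apply_severity, params = p, effects = es)
  sway <- vapply(shifted, `[[`, 0, "sway_amplitude")
  sd_ <- vapply(shifted, `[[`, 0, "step_length_sd")
  trem <- vapply(shifted, `[[`, 0, "tremor_amplitude")
  cad <- vapply(shifted, `[[`, 0, "cadence")
  expect_true(all(diff(sway) > 0))
  expect_true(all(diff(sd_) > 0))
  expect_true(all(diff(trem) > 0))
  expect_true(all(diff(cad) < 0))
})

test_that("higher severity produces visibly larger lateral pelvis deviation", {
  lat_sd <- function(sv, seeds) {
    mean(vapply(seeds, function(s) {
      p <- apply_severity(short_params(), sv)
      rec <- generate_recording(p, "P", seed = s)$recording
      com_std(list(joints = rec$joints))
    }, 0))
  }
  expect_gt(lat_sd(1.0, 1:10), lat_sd(0.2, 1:10))
})

test_that("tremor noise is spectrally confined to its band", {
  n <- 6000; fs <- 60; band <- c(15, 29)
  x <- ataxgait:::with_seed(5, band_limited_noise(n, fs, band, 0.001))
  spec <- Mod(stats::fft(x))^2
  f <- pmin((seq_len(n) - 1) * fs / n, fs - (seq_len(n) - 1) * fs / n)
  inband <- sum(spec[f >= band[1] & f <= band[2]])
  expect_gt(inband / sum(spec), 0.99)
  expect_equal(sqrt(mean(x^2)), 0.001, tolerance = 1e-9)
})

test_that("measurement noise helper perturbs at the requested scale", {
  rec <- fix_walk()$recording
  noisy <- add_position_noise(rec, 0.002, seed = 3L)
  d <- noisy$joints$pelvis - rec$joints$pelvis
  expect_equal(stats::sd(d), 0.002, tolerance = 0.05)
  expect_identical(add_position_noise(rec, 0.002, seed = 3L), noisy)
})
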