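flat_track <- function(n, x = 0, y = 0, z = 0) {
  cbind(x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n))
}

test_that("cadence is interval-based steps per minute", {
  n <- 400; fs <- 60
  # 11 pooled contacts spanning exactly 6 s (360 samples)
  seg <- make_segment(list(left_foot = flat_track(n),
                           right_foot = flat_track(n, z = 0.2),
                           pelvis = flat_track(n, y = 0.9)),
                      left = seq(1L, 361L, by = 72L),
                      right = seq(37L, 361L, by = 72L))
  expect_equal(step_cadence(seg), 100)
  single <- make_segment(list(left_foot = flat_track(n),
                              right_foot = flat_track(n, z = 0.2),
                              pelvis = flat_track(n, y = 0.9)),
                         left = 5L)
  expect_error(step_cadence(single), "insufficient steps")
})

test_that("cadence on synthetic gait matches the generator setting", {
  gt <- generate_recording(short_params(cadence = 110), "P", seed = 4L)
  fc <- detect_foot_contacts(gt$recording)
  segs <- segment_straight_walks(gt$recording,
                                 detect_turns(gt$recording), fc)
  cad <- step_cadence(segs[[1]])
  expect_equal(cad, 110, tolerance = 2 / 110)
})

test_that("step length is the median adjacent-contact distance", {
  n <- 300
  lf <- flat_track(n); rf <- flat_track(n, z = 0)
  # place contacts with known positions: left at x=0, right at x=0.6
  rf[, 1] <- 0.6
  seg <- make_segment(list(left_foot = lf, right_foot = rf,
                           pelvis = flat_track(n, y = 0.9)),
                      left = 10L, right = 100L)
  expect_equal(step_length(seg), 0.6)

  # distances {0.5, 0.6, 0.7} -> median 0.6
  lf2 <- flat_track(n); rf2 <- flat_track(n)
  lf2[1:50, 1] <- 0; rf2[1:110, 1] <- 0.5
  lf2[51:170, 1] <- 1.1; rf2[111:230, 1] <- 1.8
  lf2[171:n, 1] <- 1.1
  rf2[231:n, 1] <- 1.8
  seg2 <- make_segment(list(left_foot = lf2, right_foot = rf2,
                            pelvis = flat_track(n, y = 0.9)),
                       left = c(10L, 150L), right = c(80L, 220L))
  # pairs: L10->R80 (0.5), R80->L150 (0.6), L150->R220 (0.7)
  expect_equal(step_length(seg2), 0.6)
})

test_that("synthetic step length recovers the configured mean", {
  gt <- generate_recording(short_params(step_length_sd = 0), "P", seed = 6L)
  fc <- detect_foot_contacts(gt$recording)
  segs <- segment_straight_walks(gt$recording,
                                 detect_turns(gt$recording), fc)
  expect_equal(step_length(segs[[1]]), 0.65, tolerance = 0.01 / 0.65)
})

test_that("step trajectory equals an independent polyline summation", {
  gt <- generate_recording(short_params(), "P", seed = 12L)
  fc <- detect_foot_contacts(gt$recording)
  seg <- segment_straight_walks(gt$recording,
                                detect_turns(gt$recording), fc)[[1]]
  st <- ataxgait:::segment_steps(seg)
  arcs <- vapply(seq_len(nrow(st)), function(i) {
    joint <- seg$joints[[paste0(st$to_foot[i], "_foot")]]
    rows <- (st$from_sample[i]:st$to_sample[i]) - seg$start + 1L
    path <- joint[rows, , drop = FALSE]
    # brute force: explicit loop over consecutive sample pairs
    tot <- 0
    for (k in 2:nrow(path)) tot <- tot + sqrt(sum((path[k, ] - path[k - 1, ])^2))
    tot
  }, 0)
  expect_equal(step_trajectory(seg), median(arcs), tolerance = 1e-12)
})

test_that("step trajectory handles straight, polyline and circular swings", {
  n <- 200
  # straight-line swing: arc equals chord
  lf <- flat_track(n)
  lf[, 1] <- seq(0, 1, length.out = n)
  seg <- make_segment(list(left_foot = lf, right_foot = flat_track(n, x = 1),
                           pelvis = flat_track(n, y = 0.9)),
                      left = c(1L, n), right = integer())
  expect_equal(step_trajectory(seg), 1, tolerance = 1e-9)

  # two-segment polyline: (0,0,0) -> (0.3,0.1,0) -> (0.6,0,0)
  lf2 <- rbind(flat_track(1),
               cbind(0.3, 0.1, 0),
               cbind(0.6, 0, 0))
  seg2 <- make_segment(list(left_foot = lf2,
                            right_foot = flat_track(3, x = 0.6),
                            pelvis = flat_track(3, y = 0.9)),
                       left = c(1L, 3L), right = integer())
  expect_equal(step_trajectory(seg2), 2 * sqrt(0.09 + 0.01),
               tolerance = 1e-12)

  # finely sampled semicircle of radius r: arc length pi * r
  r <- 0.5
  th <- seq(0, pi, length.out = 500)
  lf3 <- cbind(x = r * (1 - cos(th)), y = r * sin(th), z = 0)
  seg3 <- make_segment(list(left_foot = lf3,
                            right_foot = flat_track(500, x = 2 * r),
                            pelvis = flat_track(500, y = 0.9)),
                       left = c(1L, 500L), right = integer())
  expect_equal(step_trajectory(seg3), pi * r, tolerance = 0.01)
})

test_that("relative step length follows chord/arc arithmetic and errors", {
  expect_equal(relative_step_length(0.6, 0.6), 1.0)
  expect_equal(relative_step_length(0.6, 0.75), 0.8)
  expect_error(relative_step_length(0.6, 0), "positive")
  expect_error(relative_step_length(0.7, 0.6), "invariant")
})

test_that("severe ataxia lowers the cohort's median step optimality", {
  es <- effect_sizes()
  healthy <- generate_cohort(10, 0, base_params = short_params(),
                             effects = es, seed = 61L)
  ataxic <- generate_cohort(0, 10, c(1, 1), short_params(), es, seed = 62L)
  fh <- suppressWarnings(cohort_features(healthy, max_contacts = 16L))
  fa <- suppressWarnings(cohort_features(ataxic, max_contacts = 16L))
  expect_lt(median(fa$relative_step_length),
            median(fh$relative_step_length))
})

test_that("com_std measures lateral deviation around the travel direction", {
  n <- 1200; ts <- (seq_len(n) - 1) / 60
  # exact straight line -> 0
  straight <- list(joints = list(pelvis = cbind(1.2 * ts, 0.9, 0.3 * ts)))
  expect_lt(com_std(straight), 1e-12)
  # lateral sinusoid of amplitude a on straight progress -> a / sqrt(2)
  a <- 0.03
  sine <- list(joints = list(pelvis = cbind(1.2 * ts, 0.9,
                                            a * sin(2 * pi * 1.8 * ts))))
  expect_equal(com_std(sine), a / sqrt(2), tolerance = 0.02)
})

test_that("band energies localise spectral content correctly", {
  n <- 1200; fs <- 60; ts <- (seq_len(n) - 1) / fs
  base <- list(left_foot = flat_track(n), right_foot = flat_track(n, z = 0.2))

  # constant-velocity trajectory: zero acceleration, zero energy
  seg0 <- make_segment(c(base, list(pelvis = cbind(1.2 * ts, 0.9, 0))))
  expect_equal(band_energy(seg0, c(3, 15)), 0, tolerance = 1e-18)
  expect_equal(band_energy(seg0, c(15, 29)), 0, tolerance = 1e-18)

  # pure 10 Hz positional sinusoid: energy concentrated in [3, 15]
  seg10 <- make_segment(c(base, list(pelvis = cbind(0.001 *
    sin(2 * pi * 10 * ts), 0.9, 0))))
  lo <- band_energy(seg10, c(3, 15))
  hi <- band_energy(seg10, c(15, 29))
  tot <- band_energy(seg10, c(0.01, 29.99))
  expect_gt(lo / tot, 0.99)
  expect_lt(hi / tot, 0.01)

  # white-noise acceleration: band energies proportional to bandwidth
  n2 <- 6000
  acc <- ataxgait:::with_seed(7, rnorm(n2))
  pos <- cumsum(cumsum(acc)) / 60^2  # double-integrated so 2nd diff = acc
  segw <- make_segment(list(left_foot = flat_track(n2),
                            right_foot = flat_track(n2, z = 0.2),
                            pelvis = cbind(pos, 0.9, 0)))
  ratio <- band_energy(segw, c(3, 15)) / band_energy(segw, c(15, 29))
  expect_equal(ratio, 12 / 14, tolerance = 0.1)

  # Parseval: the two bands never exceed the total
  seg <- make_segment(c(base, list(pelvis = cbind(0.01 *
    sin(2 * pi * 7 * ts) + 0.002 * sin(2 * pi * 22 * ts), 0.9, 0))))
  expect_lte(band_energy(seg, c(3, 15)) + band_energy(seg, c(15, 29)),
             band_energy(seg, c(0.01, 29.99)) + 1e-9)

  short_seg <- make_segment(list(left_foot = flat_track(30),
                                 right_foot = flat_track(30, z = 0.2),
                                 pelvis = flat_track(30, y = 0.9)))
  expect_error(band_energy(short_seg, c(3, 15)), "too short")
})

test_that("extract_features assembles a valid, deterministic vector", {
  gt <- generate_recording(short_params(), "P", seed = 14L)
  fc <- detect_foot_contacts(gt$recording)
  seg <- segment_straight_walks(gt$recording,
                                detect_turns(gt$recording), fc)[[1]]
  fv <- extract_features(seg, "seg1")
  expect_identical(extract_features(seg, "seg1"), fv)
  expect_true(all(is.finite(unlist(fv[ataxgait:::feature_columns()]))))
  expect_gt(fv$cadence, 0)
  expect_gt(fv$relative_step_length, 0)
  expect_lte(fv$relative_step_length, 1)
  expect_gte(fv$energy_low, 0)
  expect_gte(fv$energy_high, 0)
})

test_that("feature invariants hold across a seeded cohort", {
  ft <- fix_features()
  expect_true(all(ft$relative_step_length > 0 &
                    ft$relative_step_length <= 1))
  expect_true(all(is.finite(as.matrix(ft[ataxgait:::feature_columns()]))))
})

test_that("severity-coupled features rise monotonically with severity", {
  sevs <- c(0, 0.25, 0.5, 0.75, 1)
  per_sev <- lapply(sevs, function(sv) {
    p <- if (sv > 0) apply_severity(short_params(), sv) else short_params()
    coh <- lapply(1:10, function(i) {
      generate_recording(p, sprintf("P%02d", i),
                         seed = 7000L + 100L * i + round(100 * sv))
    })
    ft <- suppressWarnings(cohort_features(coh, max_contacts = 16L))
    c(com = mean(ft$com_std),
      slcv = stats::sd(ft$step_length) / mean(ft$step_length),
      ehigh = mean(ft$energy_high))
  })
  m <- do.call(rbind, per_sev)
  for (col in colnames(m)) {
    expect_gt(stats::cor(sevs, m[, col], method = "spearman"), 0)
  }
})
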