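# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# short single-pass healthy parameters used by most unit tests
short_params <- function(walk_length = 30, n_passes = 1, ...) {
  gait_params(walk_length = walk_length, n_passes = n_passes, ...)
}

# one default-parameter two-pass walk with ground truth
fix_walk <- function() {
  cached("walk", generate_recording(gait_params(), "W01", seed = 11L))
}

# a small mixed cohort and its feature table
fix_cohort <- function() {
  cached("cohort", generate_cohort(6, 7, c(0.25, 1), short_params(),
                                   seed = 21L))
}

fix_features <- function() {
  cached("features",
         suppressWarnings(cohort_features(fix_cohort(), max_contacts = 16L)))
}

# hand-built recording: constant-velocity straight walk (no real gait),
# used for turn-detection null cases
straight_recording <- function(n = 600, fs = 60, v = 1.2) {
  ts <- (seq_len(n) - 1) / fs
  line <- cbind(x = v * ts, y = 0, z = 0)
  pelvis <- cbind(x = v * ts, y = 0.95, z = 0)
  motion_recording("S01", "healthy", 0, fs,
                   list(left_foot = line, right_foot = cbind(v * ts, 0, 0.2),
                        pelvis = pelvis))
}

# build a gait_segment directly from joint tracks and contact indices
make_segment <- function(joints, left = integer(), right = integer(),
                         fs = 60) {
  n <- nrow(joints[[1]])
  rec <- motion_recording("M01", "healthy", 0, fs, joints)
  contacts <- structure(list(left = as.integer(left),
                             right = as.integer(right)),
                        class = "foot_contacts")
  ataxgait:::new_gait_segment(rec, contacts, 1L, n + 1L)
}

# two well-separated Gaussian blobs in 6-D (separation in units of sd)
blob_data <- function(n_per = 30, separation = 10, seed = 5) {
  ataxgait:::with_seed(seed, {
    a <- matrix(rnorm(n_per * 6), n_per, 6)
    b <- matrix(rnorm(n_per * 6), n_per, 6)
    b[, 1] <- b[, 1] + separation
    list(x = rbind(a, b),
         y = factor(rep(c("healthy", "ataxic"), each = n_per)))
  })
}
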