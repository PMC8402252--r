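# Synthetic gait generator: a kinematic swing/stance model with analytically
# known foot contacts, per-step lengths and turn intervals, so that the
# detection and feature stages can be tested against exact ground truth.

FOOT_SEPARATION <- 0.2   # lateral distance between foot centrelines, metres
PELVIS_HEIGHT <- 0.95    # nominal pelvis height, metres
SWING_WOBBLE_GAIN <- 1.5 # swing lateral deviation per unit sway amplitude
TURN_SWING_S <- 0.5      # duration of each in-turn repositioning swing, s
LEAD_S <- 0.6            # standing margin at recording start/end, s

#' Generate one synthetic motion-capture gait recording
#'
#' Simulates a walk of `params$walk_length` metres split into
#' `params$n_passes` straight passes separated by 180-degree turns. Feet
#' alternate single-foot swings: the swinging foot advances with a cycloid
#' horizontal profile (zero velocity at lift-off and landing), a sinusoidal
#' vertical lift of height `step_height`, and a lateral half-sine deviation
#' proportional to `sway_amplitude`; the stance foot is stationary. Each
#' step's landing point is placed at a drawn 3-D distance (truncated normal)
#' from the stance foot's contact, so drawn step lengths are exactly the
#' adjacent-contact distances a feature extractor should recover. The pelvis
#' (centre-of-mass proxy) is the stride-window moving average of the feet
#' midpoint plus a lateral sway sinusoid at step frequency and a band-limited
#' tremor component.
#'
#' @param params A [gait_params()] object.
#' @param participant_id Participant identifier string.
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   output.
#' @param label Class label, `"healthy"` or `"ataxic"`. Defaults to
#'   `"ataxic"` when `params$severity > 0`.
#' @return A list with components `recording` (a `motion_recording`: joints
#'   `left_foot`, `right_foot`, `pelvis` as `n x 3` matrices of metres,
#'   columns x/y/z with y vertical) and `truth` (a `gait_truth`: `contacts`
#'   data frame of stance onsets with 1-based sample indices, `turn_intervals`
#'   as half-open `[start, end)` sample intervals, `steps` with the drawn
#'   per-step lengths and the contact rows they join, and `per_step_lengths`).
#' @examples
#' gt <- generate_recording(gait_params(walk_length = 20, n_passes = 1),
#'                          "P01", seed = 1)
#' gt$recording
#' head(gt$truth$contacts)
#' @export
generate_recording <- function(params, participant_id = "P01", seed = 1L,
                               label = NULL) {
  validate_gait_params(params)
  if (params$step_length_mean <= FOOT_SEPARATION + 0.05) {
    stopf("invalid gait_params: field 'step_length_mean' must exceed the %.2f m foot separation",
          FOOT_SEPARATION)
  }
  label <- label %||% if (params$severity > 0) "ataxic" else "healthy"
  label <- match.arg(label, c("healthy", "ataxic"))

  fs <- params$sampling_rate
  t_step <- 60 / params$cadence
  pass_len <- params$walk_length / params$n_passes
  m_steps <- max(3L, as.integer(round(pass_len / params$step_length_mean)))
  lb <- FOOT_SEPARATION + 0.01  # feasible lower bound for a 3-D step distance

  draws <- with_seed(seed, {
    d <- draw_step_lengths(m_steps * params$n_passes,
                           params$step_length_mean, params$step_length_sd, lb)
    # tremor noise drawn after step lengths; length fixed later by resampling
    # is avoided: draw once at final length, so compute the timeline first
    d
  })

  # --- timeline construction -------------------------------------------------
  sep2 <- FOOT_SEPARATION / 2
  xL <- 0; xR <- 0
  zc <- 0                       # current pass centreline
  zL <- zc + sep2; zR <- zc - sep2
  heading <- 1
  t <- LEAD_S
  events <- list(left = list(), right = list())
  contacts <- list()
  steps <- list()
  turns <- list()

  add_contact <- function(foot, time, x, z, pass, in_turn) {
    contacts[[length(contacts) + 1L]] <<- data.frame(
      foot = foot, time_s = time, x = x, y = 0, z = z,
      pass = pass, in_turn = in_turn, stringsAsFactors = FALSE)
    length(contacts)
  }
  add_event <- function(foot, t0, t1, from_x, from_z, to_x, to_z, height,
                        wobble) {
    events[[foot]][[length(events[[foot]]) + 1L]] <<- list(
      t0 = t0, t1 = t1, from_x = from_x, from_z = from_z,
      to_x = to_x, to_z = to_z, height = height, wobble = wobble)
  }

  # initial double stance
  cid_L <- add_contact("left", 0, xL, zL, 1L, FALSE)
  cid_R <- add_contact("right", 0, xR, zR, 1L, FALSE)

  k <- 0L
  for (p in seq_len(params$n_passes)) {
    swing_left <- TRUE
    for (s in seq_len(m_steps)) {
      k <- k + 1L
      d <- draws[k]
      adv <- sqrt(d^2 - FOOT_SEPARATION^2)
      if (swing_left) {
        x_new <- xR + heading * adv
        wob <- SWING_WOBBLE_GAIN * params$sway_amplitude
        add_event("left", t, t + t_step, xL, zL, x_new, zL,
                  params$step_height, wob)
        xL <- x_new
        cid <- add_contact("left", t + t_step, xL, zL, p, FALSE)
        steps[[k]] <- data.frame(pass = p, foot = "left", length = d,
                                 stance_contact = cid_R, landing_contact = cid)
        cid_L <- cid
      } else {
        x_new <- xL + heading * adv
        wob <- -SWING_WOBBLE_GAIN * params$sway_amplitude
        add_event("right", t, t + t_step, xR, zR, x_new, zR,
                  params$step_height, wob)
        xR <- x_new
        cid <- add_contact("right", t + t_step, xR, zR, p, FALSE)
        steps[[k]] <- data.frame(pass = p, foot = "right", length = d,
                                 stance_contact = cid_L, landing_contact = cid)
        cid_R <- cid
      }
      swing_left <- !swing_left
      t <- t + t_step
    }
    if (p < params$n_passes) {
      # 180-degree heading reversal: each foot takes one quick repositioning
      # swing to the start position of the next pass, offset laterally so the
      # pelvis heading sweeps through half a circle.
      t_turn0 <- t
      turns[[length(turns) + 1L]] <- c(t_turn0, t_turn0 + params$turn_duration)
      zc_new <- zc + 2 * 0.3  # next corridor lane, 0.6 m over
      heading <- -heading
      zL_new <- zc_new + sep2; zR_new <- zc_new - sep2
      xm <- (xL + xR) / 2
      tA <- t_turn0 + 0.2
      add_event("left", tA, tA + TURN_SWING_S, xL, zL, xm, zL_new,
                params$step_height, 0)
      add_contact("left", tA + TURN_SWING_S, xm, zL_new, p + 1L, TRUE)
      tB <- t_turn0 + params$turn_duration - 0.2 - TURN_SWING_S
      add_event("right", tB, tB + TURN_SWING_S, xR, zR, xm, zR_new,
                params$step_height, 0)
      cid_R2 <- add_contact("right", tB + TURN_SWING_S, xm, zR_new,
                            p + 1L, TRUE)
      xL <- xm; xR <- xm; zL <- zL_new; zR <- zR_new; zc <- zc_new
      cid_L <- length(contacts) - 1L
      cid_R <- cid_R2
      t <- t_turn0 + params$turn_duration
    }
  }
  total_t <- t + LEAD_S
  n <- as.integer(floor(total_t * fs)) + 1L
  ts <- (seq_len(n) - 1) / fs

  # --- evaluate foot tracks --------------------------------------------------
  left <- evaluate_foot_track(events$left, c(0, zL0 = 0 + sep2), ts)
  right <- evaluate_foot_track(events$right, c(0, -sep2), ts)

  # --- pelvis ----------------------------------------------------------------
  w <- as.integer(round(2 * t_step * fs)); if (w %% 2L == 0L) w <- w + 1L
  mid_x <- moving_average((left[, 1] + right[, 1]) / 2, w)
  mid_z <- moving_average((left[, 3] + right[, 3]) / 2, w)
  perp <- horizontal_perp(mid_x, mid_z)
  f_step <- params$cadence / 60
  sway <- params$sway_amplitude * sin(2 * pi * f_step * ts)
  tremor <- with_seed(derive_seed(seed, 7919L), {
    band_limited_noise(n, fs, params$tremor_band, params$tremor_amplitude)
  })
  lat <- sway + tremor
  pel_x <- mid_x + lat * perp[, 1]
  pel_z <- mid_z + lat * perp[, 2]
  pel_y <- PELVIS_HEIGHT + 0.012 * sin(2 * pi * f_step * ts)
  pelvis <- cbind(x = pel_x, y = pel_y, z = pel_z)

  rec <- motion_recording(
    participant_id = participant_id, label = label,
    severity = params$severity, sampling_rate = fs,
    joints = list(left_foot = left, right_foot = right, pelvis = pelvis))

  contacts <- do.call(rbind, contacts)
  contacts$sample <- time_to_sample(contacts$time_s, fs)
  contacts <- contacts[, c("foot", "sample", "time_s", "x", "y", "z",
                           "pass", "in_turn")]
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(pass = integer(), foot = character(), length = numeric(),
               stance_contact = integer(), landing_contact = integer())
  turn_iv <- if (length(turns)) {
    data.frame(start = time_to_sample(vapply(turns, `[`, 0, 1L), fs),
               end = time_to_sample(vapply(turns, `[`, 0, 2L), fs))
  } else data.frame(start = integer(), end = integer())

  truth <- structure(list(contacts = contacts, turn_intervals = turn_iv,
                          steps = steps, per_step_lengths = steps$length,
                          n_samples = n),
                     class = "gait_truth")
  list(recording = rec, truth = truth)
}

# first 1-based sample index whose time is >= t
time_to_sample <- function(t, fs) {
  as.integer(ceiling(t * fs - 1e-9)) + 1L
}

# truncated-normal step distances; exact (quantile method), degenerate sd = 0
# returns the mean
draw_step_lengths <- function(n, mean, sd, lower) {
  if (mean <= lower) stopf("step_length_mean %.3f below feasible bound %.3f",
                           mean, lower)
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

# piecewise evaluation of one foot's track from its swing events
evaluate_foot_track <- function(evts, init_xz, ts) {
  n <- length(ts)
  x <- rep(init_xz[1], n); y <- numeric(n); z <- rep(init_xz[2], n)
  for (ev in evts) {
    during <- which(ts >= ev$t0 & ts < ev$t1)
    after <- which(ts >= ev$t1)
    if (length(during)) {
      tau <- (ts[during] - ev$t0) / (ev$t1 - ev$t0)
      prog <- tau - sin(2 * pi * tau) / (2 * pi)
      x[during] <- ev$from_x + (ev$to_x - ev$from_x) * prog
      z[during] <- ev$from_z + (ev$to_z - ev$from_z) * prog +
        ev$wobble * sin(pi * tau)
      y[during] <- ev$height * (1 - cos(2 * pi * tau)) / 2
    }
    if (length(after)) {
      x[after] <- ev$to_x; z[after] <- ev$to_z; y[after] <- 0
    }
  }
  cbind(x = x, y = y, z = z)
}

# unit horizontal perpendicular (left of travel) of a smoothed 2-D track;
# samples with negligible speed inherit the last moving direction
horizontal_perp <- function(px, pz) {
  n <- length(px)
  vx <- c(diff(px), 0); vz <- c(diff(pz), 0)
  sp <- sqrt(vx^2 + vz^2)
  good <- sp > 1e-9
  idx <- cummax(ifelse(good, seq_len(n), 0L))
  ux <- ifelse(idx > 0L, vx[pmax(idx, 1L)] / sp[pmax(idx, 1L)], 1)
  uz <- ifelse(idx > 0L, vz[pmax(idx, 1L)] / sp[pmax(idx, 1L)], 0)
  cbind(-uz, ux)
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise passed through an ideal (FFT brick-wall) band-pass
#' filter and rescaled to a target RMS amplitude. Used for the tremor
#' component of the synthetic pelvis track; by construction its periodogram
#' energy is confined to `band`.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 Hz interval (within `(0, fs/2)`).
#' @param rms Target root-mean-square amplitude; 0 returns zeros.
#' @return Numeric vector of length `n`. Uses the current RNG state.
#' @export
band_limited_noise <- function(n, fs, band, rms) {
  if (rms == 0 || n < 8L) return(numeric(n))
  w <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f_alias <- pmin(f, fs - f)
  keep <- f_alias >= band[1] & f_alias <= band[2]
  spec <- fft(w)
  spec[!keep] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(numeric(n))
  x * rms / s
}

#' Generate a seeded cohort of healthy and ataxic recordings
#'
#' Healthy participants are drawn at severity 0 from `base_params`; ataxic
#' participants get severities drawn uniformly from `severity_range`, mapped
#' to generator parameters through [apply_severity()] (monotone in severity).
#' Per-recording seeds are derived deterministically from `seed`.
#'
#' @param n_healthy,n_ataxic Participant counts (>= 1, or 0 to omit a group).
#' @param severity_range Length-2 interval the ataxic severities are drawn
#'   from (may be degenerate, e.g. `c(1, 1)`).
#' @param base_params Healthy-archetype [gait_params()].
#' @param effects [effect_sizes()] coupling severity to the generator.
#' @param seed Master integer seed.
#' @param subject_cv Named coefficients of variation for the between-subject
#'   parameter heterogeneity (log-normal multiplicative jitter applied to
#'   each participant's base parameters before the severity shift). Without
#'   it every participant would be statistically identical and any severity
#'   shift trivially detectable; the defaults give healthy gait parameters
#'   the within-group spread of a small adult cohort.
#' @return A list of `list(recording, truth)` entries, healthy first,
#'   participant ids `H01..`/`A01..`.
#' @examples
#' coh <- generate_cohort(2, 3, c(0.5, 1),
#'                        gait_params(walk_length = 20, n_passes = 1),
#'                        seed = 1)
#' table(vapply(coh, function(r) r$recording$label, ""))
#' @export
generate_cohort <- function(n_healthy, n_ataxic,
                            severity_range = c(0.25, 1),
                            base_params = gait_params(),
                            effects = effect_sizes(),
                            seed = 1L,
                            subject_cv = c(cadence = 0.025,
                                           step_length = 0.04,
                                           step_height = 0.08,
                                           sway = 0.12,
                                           step_sd = 0.15,
                                           tremor = 0.15)) {
  if (n_healthy < 0 || n_ataxic < 0 || n_healthy + n_ataxic < 1) {
    stopf("cohort needs at least one participant")
  }
  if (n_ataxic > 0 && (length(severity_range) != 2L ||
                       any(!is.finite(severity_range)) ||
                       severity_range[2] < severity_range[1])) {
    stopf("severity_range must be a non-empty interval when n_ataxic > 0")
  }
  n <- n_healthy + n_ataxic
  sev <- if (n_ataxic > 0) {
    with_seed(derive_seed(seed, 1L),
              runif(n_ataxic, severity_range[1], severity_range[2]))
  } else numeric(0)
  jitter <- with_seed(derive_seed(seed, 2L),
                      matrix(rnorm(n * 6L), n, 6L,
                             dimnames = list(NULL, names(subject_cv))))
  subject_params <- function(i) {
    p <- base_params
    mult <- exp(subject_cv * jitter[i, ])  # median-preserving log-normal
    p$cadence <- p$cadence * mult[["cadence"]]
    p$step_length_mean <- p$step_length_mean * mult[["step_length"]]
    p$step_height <- p$step_height * mult[["step_height"]]
    p$sway_amplitude <- p$sway_amplitude * mult[["sway"]]
    p$step_length_sd <- p$step_length_sd * mult[["step_sd"]]
    p$tremor_amplitude <- p$tremor_amplitude * mult[["tremor"]]
    p
  }
  out <- vector("list", n)
  i <- 0L
  for (h in seq_len(n_healthy)) {
    i <- i + 1L
    out[[i]] <- generate_recording(subject_params(i),
                                   participant_id = sprintf("H%02d", h),
                                   seed = derive_seed(seed, 100L + i),
                                   label = "healthy")
  }
  for (a in seq_len(n_ataxic)) {
    i <- i + 1L
    p <- apply_severity(subject_params(i), sev[a], effects)
    out[[i]] <- generate_recording(p,
                                   participant_id = sprintf("A%02d", a),
                                   seed = derive_seed(seed, 100L + i),
                                   label = "ataxic")
  }
  out
}

#' Add Gaussian measurement noise to a recording
#'
#' Perturbs every joint coordinate with i.i.d. Gaussian noise, emulating
#' sensor position error.
#'
#' @param recording A `motion_recording`.
#' @param sd Noise standard deviation in metres.
#' @param seed Integer seed.
#' @return The perturbed recording.
#' @export
add_position_noise <- function(recording, sd, seed = 1L) {
  stopifnot(inherits(recording, "motion_recording"))
  with_seed(seed, {
    recording$joints <- lapply(recording$joints, function(m) {
      m + matrix(rnorm(length(m), 0, sd), nrow(m), ncol(m))
    })
  })
  recording
}
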