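# The six per-segment gait features: cadence, step length (SL), step
# trajectory (ST), relative step length (SL/ST), centre-of-mass lateral
# standard deviation, and acceleration energy in two spectral bands.

ENERGY_BAND_LOW <- c(3, 15)
ENERGY_BAND_HIGH <- c(15, 29)

# positions of a foot at an absolute sample index inside a segment
segment_joint <- function(segment, joint, samples) {
  rel <- samples - segment$start + 1L
  segment$joints[[joint]][rel, , drop = FALSE]
}

# time-ordered pooled contacts of a segment, duplicates in time collapsed to
# distinct rows; consecutive pairs with zero time gap are not usable as steps
segment_pooled_contacts <- function(segment) {
  pooled_contacts(segment$contacts, segment$start, segment$end)
}

#' Step cadence of a segment
#'
#' Steps per minute, computed interval-wise as
#' `(pooled contact count - 1) / elapsed time` between the first and last
#' pooled stance onsets. Interval counting avoids the upward bias a raw
#' count-per-duration estimate has on short segments.
#'
#' @param segment A `gait_segment`.
#' @return Cadence in steps/minute.
#' @export
step_cadence <- function(segment) {
  pc <- segment_pooled_contacts(segment)
  if (nrow(pc) < 2L) stopf("insufficient steps: need >= 2 pooled contacts")
  dt <- (pc$sample[nrow(pc)] - pc$sample[1]) / segment$sampling_rate
  if (dt <= 0) stopf("insufficient steps: contacts span no time")
  (nrow(pc) - 1L) / dt * 60
}

# per-step table of a segment: consecutive pooled contacts with positive time
# gap; each row one step ending at the later contact (the swinging foot)
segment_steps <- function(segment) {
  pc <- segment_pooled_contacts(segment)
  if (nrow(pc) < 2L) stopf("insufficient steps: need >= 2 pooled contacts")
  from <- pc[-nrow(pc), ]
  to <- pc[-1L, ]
  ok <- to$sample > from$sample
  data.frame(from_foot = from$foot[ok], from_sample = from$sample[ok],
             to_foot = to$foot[ok], to_sample = to$sample[ok])
}

#' Step length of a segment
#'
#' Median over steps of the 3-D Euclidean distance between adjacent foot
#' contacts: the position of the earlier contacting foot at its contact
#' sample and of the later contacting foot at its own.
#'
#' @param segment A `gait_segment`.
#' @return Step length in metres (median over the segment's steps).
#' @export
step_length <- function(segment) {
  st <- segment_steps(segment)
  if (nrow(st) < 1L) stopf("insufficient steps: no positive-duration steps")
  d <- vapply(seq_len(nrow(st)), function(i) {
    p0 <- segment_joint(segment, paste0(st$from_foot[i], "_foot"),
                        st$from_sample[i])
    p1 <- segment_joint(segment, paste0(st$to_foot[i], "_foot"),
                        st$to_sample[i])
    sqrt(sum((p1 - p0)^2))
  }, 0)
  median(d)
}

#' Step trajectory of a segment
#'
#' Median over steps of the arc length of the swinging foot's sampled path
#' between adjacent contacts: the sum of Euclidean distances between
#' consecutive samples of the foot that lands at the later contact.
#'
#' @param segment A `gait_segment`.
#' @return Step trajectory (arc length) in metres.
#' @export
step_trajectory <- function(segment) {
  st <- segment_steps(segment)
  if (nrow(st) < 1L) stopf("insufficient steps: no positive-duration steps")
  a <- vapply(seq_len(nrow(st)), function(i) {
    path <- segment_joint(segment, paste0(st$to_foot[i], "_foot"),
                          st$from_sample[i]:st$to_sample[i])
    polyline_length(path)
  }, 0)
  median(a)
}

# arc length of an n x 3 polyline
polyline_length <- function(path) {
  if (nrow(path) < 2L) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

#' Relative step length
#'
#' The ratio SL/ST measuring step optimality: 1 means the foot travelled the
#' straight-line minimum distance. The chord-vs-arc geometry bounds it by 1;
#' a violation beyond `1e-9` indicates inconsistent inputs and is an error,
#' never silently clipped.
#'
#' @param SL Step length, metres.
#' @param ST Step trajectory, metres.
#' @return The dimensionless ratio in `(0, 1]`.
#' @export
relative_step_length <- function(SL, ST) {
  if (!is.finite(ST) || ST <= 0) stopf("step trajectory must be positive")
  if (SL > ST * (1 + 1e-9)) {
    stopf("invariant violation: step length %.6g exceeds step trajectory %.6g",
          SL, ST)
  }
  min(SL / ST, 1)
}

#' Lateral centre-of-mass standard deviation
#'
#' The pelvis horizontal track is rotated so its first principal axis is the
#' direction of forward progress; the standard deviation of the orthogonal
#' horizontal coordinate measures body sway, uncontaminated by the forward
#' trend.
#'
#' @param segment A `gait_segment` (or any object with a pelvis joint and
#'   >= 2 samples).
#' @return Standard deviation in metres.
#' @export
com_std <- function(segment) {
  pel <- segment$joints$pelvis
  if (is.null(pel) || nrow(pel) < 2L) stopf("com_std needs >= 2 pelvis samples")
  horiz <- pel[, c(1, 3)]
  pc <- prcomp(horiz, center = TRUE, scale. = FALSE)
  stats::sd(pc$x[, 2])
}

#' Band energy of the pelvis acceleration
#'
#' Acceleration is synthesised from pelvis position by second-order central
#' differences per axis; each axis is mean-removed, Hann-windowed and its
#' periodogram summed over the frequency band (half-open `(lo, hi]`, so the
#' two default bands partition their bins). Energies are summed over the
#' three axes and divided by the segment sample count. The Hann window damps
#' leakage from the dominant step harmonic into the high band.
#'
#' @param segment A `gait_segment` at 60 Hz.
#' @param band Length-2 Hz interval within `(0, 30)`.
#' @param joint Joint supplying the signal (default pelvis).
#' @return Length-normalised band energy, `(m/s^2)^2` per sample.
#' @export
band_energy <- function(segment, band, joint = "pelvis") {
  fs <- segment$sampling_rate
  pos <- segment$joints[[joint]]
  if (is.null(pos)) stopf("joint '%s' not present", joint)
  n <- nrow(pos)
  if (n < fs) stopf("segment too short for spectral estimate (< 1 s)")
  if (band[1] < 0 || band[2] > fs / 2 || band[2] <= band[1]) {
    stopf("band must be an increasing interval within (0, %g) Hz", fs / 2)
  }
  acc <- apply(pos, 2L, function(x) {
    (x[c(-1, -2)] - 2 * x[c(-1, -length(x))] + x[c(-(length(x) - 1), -length(x))]) * fs^2
  })
  m <- nrow(acc)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))  # Hann
  freqs <- (seq_len(m) - 1) * fs / m
  f_alias <- pmin(freqs, fs - freqs)
  keep <- f_alias > band[1] & f_alias <= band[2]
  e <- vapply(seq_len(ncol(acc)), function(j) {
    xw <- (acc[, j] - mean(acc[, j])) * w
    p <- Mod(fft(xw))^2 / (m * mean(w^2))
    sum(p[keep])
  }, 0)
  sum(e) / n
}

#' Extract the six-feature vector of a segment
#'
#' Assembles cadence, step length, step trajectory, relative step length,
#' lateral COM standard deviation and the two band energies, plus segment
#' metadata. Fails atomically: any sub-feature error aborts the segment with
#' its identifier attached.
#'
#' @param segment A `gait_segment`.
#' @param segment_id Optional identifier used in error messages and output.
#' @return One-row data frame with columns `participant_id`, `segment_id`,
#'   `label`, `severity`, `cadence`, `step_length`, `step_trajectory`,
#'   `relative_step_length`, `com_std`, `energy_low`, `energy_high`.
#' @export
extract_features <- function(segment, segment_id = NA_character_) {
  out <- tryCatch({
    sl <- step_length(segment)
    st <- step_trajectory(segment)
    data.frame(
      participant_id = segment$participant_id,
      segment_id = segment_id,
      label = segment$label,
      severity = segment$severity,
      cadence = step_cadence(segment),
      step_length = sl,
      step_trajectory = st,
      relative_step_length = relative_step_length(sl, st),
      com_std = com_std(segment),
      energy_low = band_energy(segment, ENERGY_BAND_LOW),
      energy_high = band_energy(segment, ENERGY_BAND_HIGH),
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stopf("feature extraction failed for segment %s: %s",
          segment_id, conditionMessage(e))
  })
  out
}

#' Full feature table for a cohort of recordings
#'
#' Runs the preprocessing chain (subsample to 60 Hz, detect turns and foot
#' contacts, cut straight segments) and feature extraction over a generated
#' or loaded cohort. Recordings in which no gait is detected are skipped
#' with a warning.
#'
#' @param cohort List of recordings, either `motion_recording` objects or
#'   `list(recording, truth)` entries as returned by [generate_cohort()].
#' @param min_contacts,max_contacts Segment contact bounds, see
#'   [segment_straight_walks()].
#' @param turn_args,contact_args Named lists of extra arguments for
#'   [detect_turns()] and [detect_foot_contacts()].
#' @return Feature data frame, one row per segment.
#' @export
cohort_features <- function(cohort, min_contacts = 4L, max_contacts = 16L,
                            turn_args = list(), contact_args = list()) {
  rows <- list()
  for (rec in cohort) {
    if (is.list(rec) && !inherits(rec, "motion_recording")) rec <- rec$recording
    rec60 <- subsample_to_60hz(rec)
    contacts <- tryCatch(
      do.call(detect_foot_contacts, c(list(rec60), contact_args)),
      error = function(e) NULL)
    if (is.null(contacts)) {
      warning(sprintf("no gait detected for %s; skipped", rec$participant_id),
              call. = FALSE)
      next
    }
    turns <- do.call(detect_turns, c(list(rec60), turn_args))
    segs <- segment_straight_walks(rec60, turns, contacts,
                                   min_contacts = min_contacts,
                                   max_contacts = max_contacts)
    for (i in seq_along(segs)) {
      sid <- sprintf("%s_s%02d", rec$participant_id, i)
      rows[[length(rows) + 1L]] <- extract_features(segs[[i]], sid)
    }
  }
  if (!length(rows)) stopf("no segments produced any features")
  do.call(rbind, rows)
}

feature_columns <- function() {
  c("cadence", "step_length", "step_trajectory", "relative_step_length",
    "com_std", "energy_low", "energy_high")
}
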