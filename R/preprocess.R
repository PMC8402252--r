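# Preprocessing: rate harmonisation, turn detection, foot-contact detection,
# and extraction of straight-gait segments with turns excluded.

#' Subsample a recording to 60 Hz
#'
#' Recordings taken at 120 Hz are low-pass filtered (zero-phase 4th-order
#' Butterworth, 29 Hz cutoff, forward-backward so contact timing is not
#' shifted) and decimated by two; 60 Hz recordings are returned unchanged.
#' The anti-alias filter matters because downstream spectral features use
#' energy up to 29 Hz.
#'
#' @param recording A `motion_recording` at 60 or 120 Hz.
#' @return The recording at 60 Hz.
#' @export
subsample_to_60hz <- function(recording) {
  validate_recording(recording)
  if (recording$sampling_rate == 60) return(recording)
  recording$joints <- lapply(recording$joints, function(m) {
    sm <- apply(m, 2L, lowpass_zerophase, cutoff_hz = 29, fs = 120,
                order = 4L)
    sm[seq(1L, nrow(sm), by = 2L), , drop = FALSE]
  })
  recording$sampling_rate <- 60
  recording$n_samples <- nrow(recording$joints[[1]])
  recording
}

#' Detect turn intervals from the pelvis heading
#'
#' The pelvis horizontal track is low-pass filtered (zero-phase Butterworth
#' at `heading_cutoff_hz`), the heading taken as the angle of its velocity,
#' and samples whose absolute heading rate exceeds
#' `heading_rate_threshold_deg_s` are dilated by `window_s` on each side and
#' merged into maximal disjoint half-open intervals. The low cutoff is
#' deliberate: lateral body sway modulates the instantaneous heading at step
#' frequency (1.5--2 Hz), while turns evolve over seconds; a 0.5 Hz cutoff
#' rejects the former and keeps the latter. Heading changes at negligible
#' speed (standing, gait initiation) are ignored, since the direction of an
#' almost-zero velocity is meaningless.
#'
#' @param recording A 60 Hz `motion_recording` with a pelvis joint.
#' @param window_s Dilation window, seconds.
#' @param heading_rate_threshold_deg_s Threshold on |d heading / dt|, deg/s.
#' @param heading_cutoff_hz Low-pass cutoff for the pelvis track, Hz.
#' @param min_speed Speed gate (m/s) below which heading changes are
#'   ignored.
#' @return Data frame with columns `start`, `end`: 1-based half-open
#'   `[start, end)` sample intervals, sorted and disjoint. Empty for straight
#'   walks or very short recordings.
#' @export
detect_turns <- function(recording, window_s = 0.5,
                         heading_rate_threshold_deg_s = 45,
                         heading_cutoff_hz = 0.5,
                         min_speed = 0.1) {
  validate_recording(recording)
  if (recording$sampling_rate != 60) {
    stopf("detect_turns expects a 60 Hz recording; call subsample_to_60hz()")
  }
  fs <- recording$sampling_rate
  n <- recording$n_samples
  if (n <= 2L * fs) return(data.frame(start = integer(), end = integer()))
  pel <- recording$joints$pelvis
  px <- lowpass_zerophase(pel[, 1], heading_cutoff_hz, fs)
  pz <- lowpass_zerophase(pel[, 3], heading_cutoff_hz, fs)
  vx <- diff(px) * fs
  vz <- diff(pz) * fs
  speed <- sqrt(vx^2 + vz^2)
  heading <- atan2(vz, vx)
  # unwrap, then rate; slow samples contribute no heading change
  dh <- diff(heading)
  dh <- (dh + pi) %% (2 * pi) - pi
  moving <- speed > min_speed
  dh[!(moving[-1] & moving[-length(moving)])] <- 0
  rate <- abs(dh) * fs * 180 / pi
  rate <- moving_average(rate, as.integer(round(0.25 * fs)))
  hot <- rate > heading_rate_threshold_deg_s
  if (!any(hot)) return(data.frame(start = integer(), end = integer()))
  dil <- as.integer(round(window_s * fs))
  idx <- which(hot) + 1L  # rate[i] sits between samples i and i+1
  lo <- pmax(idx - dil, 1L)
  hi <- pmin(idx + dil + 1L, n + 1L)  # half-open end
  merge_intervals(lo, hi)
}

# fill FALSE runs of length <= gap that are flanked by TRUE on both sides
close_mask_gaps <- function(mask, gap) {
  if (gap < 1L) return(mask)
  r <- rle(mask)
  nr <- length(r$lengths)
  fill <- !r$values & r$lengths <= gap &
    seq_len(nr) > 1L & seq_len(nr) < nr
  r$values[fill] <- TRUE
  inverse.rle(r)
}

# drop TRUE runs shorter than min_len
drop_short_runs <- function(mask, min_len) {
  if (min_len < 2L) return(mask)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

# merge overlapping/adjacent [lo, hi) intervals into maximal disjoint ones
merge_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    j <- length(out_lo)
    if (lo[i] <= out_hi[j]) {
      out_hi[j] <- max(out_hi[j], hi[i])
    } else {
      out_lo <- c(out_lo, lo[i]); out_hi <- c(out_hi, hi[i])
    }
  }
  data.frame(start = as.integer(out_lo), end = as.integer(out_hi))
}

#' Detect foot contacts (stance onsets)
#'
#' Per foot, the smoothed vertical position and smoothed speed are
#' thresholded: a sample is "grounded" when height is below
#' `minimum + contact_height_fraction * vertical range` and speed below
#' `speed_threshold`. The first sample of each grounded run is a stance
#' onset. On the synthetic model, swing velocity vanishes smoothly at
#' landing, so onsets align with ground-truth contacts to within a couple of
#' samples.
#'
#' @param recording A 60 Hz `motion_recording` with both feet present.
#' @param contact_height_fraction Height threshold as a fraction of each
#'   foot's vertical range.
#' @param speed_threshold Grounded-speed threshold, m/s.
#' @param smooth_samples Moving-average width (samples) for positions and
#'   speed.
#' @param min_gap_s,min_stance_s Mask clean-up: grounded gaps shorter than
#'   `min_gap_s` are closed and grounded runs shorter than `min_stance_s`
#'   discarded, which de-flickers the thresholding under measurement noise
#'   (both are well below the duration of a physiological swing or stance).
#' @return A list of class `foot_contacts` with strictly increasing 1-based
#'   sample indices `left` and `right`.
#' @export
detect_foot_contacts <- function(recording, contact_height_fraction = 0.1,
                                 speed_threshold = 0.05,
                                 smooth_samples = 5L,
                                 min_gap_s = 0.15, min_stance_s = 0.12) {
  validate_recording(recording)
  if (recording$sampling_rate != 60) {
    stopf("detect_foot_contacts expects a 60 Hz recording")
  }
  fs <- recording$sampling_rate
  res <- lapply(c(left = "left_foot", right = "right_foot"), function(j) {
    pos <- smooth_positions(recording$joints[[j]], smooth_samples)
    y <- pos[, 2]
    h_thr <- min(y) + contact_height_fraction * (max(y) - min(y))
    sp <- position_speed(pos, fs, halfwidth = 2L)
    grounded <- y <= h_thr & sp <= speed_threshold
    grounded <- close_mask_gaps(grounded, as.integer(round(min_gap_s * fs)))
    grounded <- drop_short_runs(grounded,
                                as.integer(round(min_stance_s * fs)))
    onsets <- which(grounded & !c(FALSE, grounded[-length(grounded)]))
    as.integer(onsets)
  })
  if (length(res$left) < 2L && length(res$right) < 2L) {
    stopf("no gait detected: fewer than 2 stance onsets on both feet")
  }
  structure(res, class = "foot_contacts")
}

#' Cut a recording into straight-gait segments
#'
#' The complement of the turn intervals is cut into maximal half-open
#' intervals; segments keeping at least `min_contacts` stance onsets (pooled
#' over both feet) are retained, optionally split further into sub-segments
#' of at most `max_contacts` pooled onsets (the study-scale configuration
#' uses this to obtain a few hundred short segments from tens of
#' recordings).
#'
#' @param recording A 60 Hz `motion_recording`.
#' @param turns Data frame of half-open turn intervals (from
#'   [detect_turns()]).
#' @param contacts A `foot_contacts` object.
#' @param min_contacts Minimum pooled onsets for a segment to be kept.
#' @param max_contacts Maximum pooled onsets per segment; `Inf` (default)
#'   keeps whole inter-turn stretches.
#' @return List of `gait_segment` objects: `start`/`end` half-open sample
#'   interval, per-foot contacts restricted to it, recording metadata.
#' @export
segment_straight_walks <- function(recording, turns, contacts,
                                   min_contacts = 4L, max_contacts = Inf) {
  validate_recording(recording)
  n <- recording$n_samples
  free <- interval_complement(turns, n)
  segs <- list()
  for (i in seq_len(nrow(free))) {
    pooled <- pooled_contacts(contacts, free$start[i], free$end[i])
    if (nrow(pooled) < min_contacts) next
    if (nrow(pooled) <= max_contacts) {
      segs[[length(segs) + 1L]] <- c(free$start[i], free$end[i])
    } else {
      # split at contact boundaries into chunks of max_contacts onsets
      starts <- seq(1L, nrow(pooled), by = max_contacts)
      for (s in starts) {
        e <- min(s + max_contacts, nrow(pooled) + 1L)
        if (e - s < min_contacts) next
        seg_start <- if (s == 1L) free$start[i] else pooled$sample[s]
        seg_end <- if (e > nrow(pooled)) free$end[i] else pooled$sample[e]
        segs[[length(segs) + 1L]] <- c(seg_start, seg_end)
      }
    }
  }
  lapply(segs, function(iv) {
    new_gait_segment(recording, contacts, iv[1], iv[2])
  })
}

new_gait_segment <- function(recording, contacts, start, end) {
  structure(list(
    start = as.integer(start), end = as.integer(end),
    contacts = list(
      left = contacts$left[contacts$left >= start & contacts$left < end],
      right = contacts$right[contacts$right >= start & contacts$right < end]),
    sampling_rate = recording$sampling_rate,
    joints = lapply(recording$joints,
                    function(m) m[start:(end - 1L), , drop = FALSE]),
    participant_id = recording$participant_id,
    label = recording$label,
    severity = recording$severity
  ), class = "gait_segment")
}

#' @export
print.gait_segment <- function(x, ...) {
  cat(sprintf(
    "<gait_segment> %s [%d, %d) %.1f s, %d contacts (%s, severity %.2f)\n",
    x$participant_id, x$start, x$end,
    (x$end - x$start) / x$sampling_rate,
    length(x$contacts$left) + length(x$contacts$right), x$label, x$severity))
  invisible(x)
}

# complement of disjoint [start, end) intervals within [1, n + 1)
interval_complement <- function(iv, n) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(data.frame(start = 1L, end = n + 1L))
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  lo <- c(1L, iv$end)
  hi <- c(iv$start, n + 1L)
  keep <- hi > lo
  data.frame(start = as.integer(lo[keep]), end = as.integer(hi[keep]))
}

# pooled, time-ordered contacts within [start, end)
pooled_contacts <- function(contacts, start = 1L, end = Inf) {
  df <- rbind(
    data.frame(foot = rep("left", length(contacts$left)),
               sample = as.integer(contacts$left)),
    data.frame(foot = rep("right", length(contacts$right)),
               sample = as.integer(contacts$right)))
  df <- df[df$sample >= start & df$sample < end, , drop = FALSE]
  df[order(df$sample, df$foot), , drop = FALSE]
}
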