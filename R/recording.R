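#' Construct a motion recording
#'
#' The container for one participant's motion-capture trial: an ordered set
#' of joint trajectories (metres, right-handed coordinates with y vertical
#' and the gait plane x--z) plus class metadata. The canonical joint set is
#' `left_foot`, `right_foot`, `pelvis`; extra joints are carried through
#' untouched.
#'
#' @param participant_id Identifier string.
#' @param label `"healthy"` or `"ataxic"`.
#' @param severity Non-negative severity score (0 for healthy).
#' @param sampling_rate 60 or 120 Hz.
#' @param joints Named list of `n x 3` numeric matrices, equal row counts,
#'   finite, containing at least the canonical joints.
#' @return A `motion_recording` object.
#' @export
motion_recording <- function(participant_id, label, severity, sampling_rate,
                             joints) {
  rec <- structure(list(participant_id = as.character(participant_id),
                        label = match.arg(label, c("healthy", "ataxic")),
                        severity = as.numeric(severity),
                        sampling_rate = as.numeric(sampling_rate),
                        joints = joints,
                        n_samples = nrow(joints[[1]])),
                   class = "motion_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (!is.list(rec$joints) || is.null(names(rec$joints))) {
    stopf("joints must be a named list of n x 3 matrices")
  }
  need <- c("left_foot", "right_foot", "pelvis")
  miss <- setdiff(need, names(rec$joints))
  if (length(miss)) stopf("recording is missing joint(s): %s",
                          paste(miss, collapse = ", "))
  ns <- vapply(rec$joints, nrow, 0L)
  if (length(unique(ns)) != 1L) stopf("joint sequences differ in length")
  if (ns[[1]] != rec$n_samples) stopf("n_samples inconsistent with joints")
  if (!all(vapply(rec$joints, function(m) ncol(m) == 3L &&
                    all(is.finite(m)), logical(1L)))) {
    stopf("joint coordinates must be finite n x 3 matrices")
  }
  if (!rec$sampling_rate %in% c(60, 120)) {
    stopf("sampling_rate must be 60 or 120 Hz, got %s", rec$sampling_rate)
  }
  invisible(rec)
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf("<motion_recording> %s (%s, severity %.2f)\n",
              x$participant_id, x$label, x$severity))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), joints: %s\n",
              x$n_samples, x$sampling_rate, x$n_samples / x$sampling_rate,
              paste(names(x$joints), collapse = ", ")))
  invisible(x)
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %d contacts, %d turn interval(s), %d steps\n",
              nrow(x$contacts), nrow(x$turn_intervals), nrow(x$steps)))
  invisible(x)
}
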