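#' Gait generator parameters
#'
#' Bundles the kinematic parameters of the synthetic gait model. The defaults
#' describe a healthy adult archetype: cadence in the normal 100--115
#' steps/minute band, 0.65 m steps, a 100 m walk split into two straight
#' passes along a 50 m corridor with a turn between them.
#'
#' @param cadence Steps per minute (> 0).
#' @param step_length_mean Mean step length in metres (> 0). A step length is
#'   the 3-D distance between adjacent (alternating-foot) ground contacts.
#' @param step_length_sd Standard deviation of the per-step length draw in
#'   metres (>= 0).
#' @param step_height Peak foot lift during swing, metres.
#' @param sway_amplitude Amplitude of the lateral centre-of-mass sinusoid,
#'   metres. Also scales the lateral deviation of the swing path (gain 1.5),
#'   so larger sway produces less straight, lower step-optimality swings.
#' @param tremor_amplitude RMS amplitude (metres) of the band-limited tremor
#'   component added to the pelvis lateral coordinate.
#' @param tremor_band Length-2 numeric, Hz interval the tremor is confined to.
#'   Upper edge must be below the output Nyquist frequency.
#' @param walk_length Total walked distance in metres.
#' @param n_passes Number of straight passes; passes are separated by
#'   180-degree turns lasting `turn_duration` seconds.
#' @param sampling_rate Sampling rate in Hz, 60 or 120.
#' @param severity Non-negative severity scalar carried as metadata
#'   (0 = healthy archetype); it does not itself alter the kinematics, see
#'   [apply_severity()].
#' @param turn_duration Turn duration in seconds.
#' @return An object of class `gait_params` (a validated list).
#' @examples
#' p <- gait_params(cadence = 110)
#' p$step_length_mean
#' @export
gait_params <- function(cadence = 110,
                        step_length_mean = 0.65,
                        step_length_sd = 0.02,
                        step_height = 0.05,
                        sway_amplitude = 0.02,
                        tremor_amplitude = 0.0002,
                        tremor_band = c(15, 29),
                        walk_length = 100,
                        n_passes = 2,
                        sampling_rate = 60,
                        severity = 0,
                        turn_duration = 2) {
  p <- list(
    cadence = cadence, step_length_mean = step_length_mean,
    step_length_sd = step_length_sd, step_height = step_height,
    sway_amplitude = sway_amplitude, tremor_amplitude = tremor_amplitude,
    tremor_band = as.numeric(tremor_band), walk_length = walk_length,
    n_passes = as.integer(n_passes), sampling_rate = sampling_rate,
    severity = severity, turn_duration = turn_duration
  )
  class(p) <- "gait_params"
  validate_gait_params(p)
  p
}

validate_gait_params <- function(p) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stopf("invalid gait_params: field '%s' %s", field, why)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$cadence) && p$cadence > 0, "cadence", "must be > 0")
  chk(num1(p$step_length_mean) && p$step_length_mean > 0,
      "step_length_mean", "must be > 0")
  chk(num1(p$step_length_sd) && p$step_length_sd >= 0,
      "step_length_sd", "must be >= 0")
  chk(num1(p$step_height) && p$step_height >= 0, "step_height", "must be >= 0")
  chk(num1(p$sway_amplitude) && p$sway_amplitude >= 0,
      "sway_amplitude", "must be >= 0")
  chk(num1(p$tremor_amplitude) && p$tremor_amplitude >= 0,
      "tremor_amplitude", "must be >= 0")
  chk(is.numeric(p$tremor_band) && length(p$tremor_band) == 2L &&
        all(is.finite(p$tremor_band)) && p$tremor_band[1] > 0 &&
        p$tremor_band[2] > p$tremor_band[1],
      "tremor_band", "must be an increasing positive Hz interval")
  chk(num1(p$walk_length) && p$walk_length > 0, "walk_length", "must be > 0")
  chk(length(p$n_passes) == 1L && p$n_passes >= 1L, "n_passes", "must be >= 1")
  chk(num1(p$sampling_rate) && p$sampling_rate %in% c(60, 120),
      "sampling_rate", "must be 60 or 120")
  chk(p$tremor_band[2] < 30, "tremor_band",
      "upper edge must be below the 60 Hz output Nyquist (30 Hz)")
  chk(num1(p$severity) && p$severity >= 0, "severity", "must be >= 0")
  chk(num1(p$turn_duration) && p$turn_duration > 0,
      "turn_duration", "must be > 0")
  # the turn must fit two 0.5 s repositioning swings plus settle margins
  chk(p$turn_duration >= 1.5, "turn_duration",
      "must be >= 1.5 s to fit the two turn repositioning swings")
  invisible(p)
}

#' Default severity effect sizes
#'
#' Multiplicative couplings between the severity scalar and the generator
#' parameters that the ataxia literature flags as discriminative: lateral
#' sway, step-length variability, high-frequency tremor, and (reduced)
#' cadence. A parameter value of `x` at severity `s` becomes
#' `x * (1 + effect * s)` (for cadence, `x * max(1 - effect * s, 0.3)`).
#' All-zero effects make ataxic recordings statistically identical to healthy
#' ones.
#'
#' @param sway Effect on `sway_amplitude`.
#' @param step_sd Effect on `step_length_sd`.
#' @param tremor Effect on `tremor_amplitude`.
#' @param cadence Fractional cadence reduction per unit severity.
#' @return Named list of class `effect_sizes`.
#' @export
effect_sizes <- function(sway = 1.5, step_sd = 1.5, tremor = 2.0,
                         cadence = 0.15) {
  es <- list(sway = sway, step_sd = step_sd, tremor = tremor,
             cadence = cadence)
  if (!all(vapply(es, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x >= 0, logical(1L)))) {
    stopf("effect sizes must be single non-negative numbers")
  }
  class(es) <- "effect_sizes"
  es
}

#' Apply a severity level to generator parameters
#'
#' Shifts the severity-coupled fields of a [gait_params()] object
#' multiplicatively and monotonically: sway, step-length variability and
#' tremor increase with severity; cadence decreases (floored at 30% of the
#' base cadence).
#'
#' @param params A `gait_params` object (the healthy archetype).
#' @param severity Non-negative severity scalar.
#' @param effects An [effect_sizes()] object.
#' @return A new `gait_params` object with `severity` recorded.
#' @export
apply_severity <- function(params, severity, effects = effect_sizes()) {
  stopifnot(inherits(params, "gait_params"))
  if (!is.numeric(severity) || length(severity) != 1L || severity < 0) {
    stopf("severity must be a single non-negative number")
  }
  p <- params
  p$sway_amplitude <- params$sway_amplitude * (1 + effects$sway * severity)
  p$step_length_sd <- params$step_length_sd * (1 + effects$step_sd * severity)
  p$tremor_amplitude <-
    params$tremor_amplitude * (1 + effects$tremor * severity)
  p$cadence <- params$cadence * max(1 - effects$cadence * severity, 0.3)
  p$severity <- severity
  validate_gait_params(p)
  p
}
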