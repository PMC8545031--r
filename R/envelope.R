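# Attack/release envelope trackers: the nonlinear one-pole recursive averagers
# that follow the top (high tracker) and bottom (low tracker) of the airway
# pressure signal. Each tracker stores a single envelope value; the attack
# coefficient governs the fast direction, the release coefficient the slow one.

#' Attack/release coefficient pair for an envelope tracker
#'
#' Bundles the attack coefficient (fast direction) and release coefficient
#' (slow direction) of a recursive envelope tracker. Both are feedback weights
#' in `[0, 1]`; the attack coefficient must not exceed the release coefficient,
#' so that the tracker responds faster in its attack direction than it decays.
#'
#' @param alpha_attack Attack coefficient, unitless fraction in `[0, 1]`.
#'   The default, `0.9^(100 / fs)`, keeps the attack-mode 1/e memory at the
#'   design value of about 100 ms at every sample rate (see
#'   [attack_time_constant()]); it is exactly 0.9 at 100 samples/s. A fixed
#'   coefficient at a lower rate would stretch the attack memory across the
#'   breath peak, so the recorded breath-cycle maximum would land on the
#'   falling limb of the waveform.
#' @param alpha_release Release coefficient, unitless fraction in
#'   `[alpha_attack, 1]`. The default is calibrated with
#'   [release_coefficient()] at `r_min = 1.5`, `r_nom = 2.4`, `t_max = 15` s
#'   and the configured `fs`.
#' @param fs Sample rate in samples/s, used to compute the coefficient
#'   defaults.
#'
#' @return An object of class `tracker_coefficients`: a list with elements
#'   `alpha_attack` and `alpha_release`.
#' @examples
#' tracker_coefficients()
#' tracker_coefficients(0.9, release_coefficient(1.5, 2.4, 15, fs = 50), fs = 50)
#' @export
tracker_coefficients <- function(alpha_attack = 0.9^(100 / fs),
                                 alpha_release = release_coefficient(fs = fs),
                                 fs = 100) {
  stopifnot(is.numeric(alpha_attack), length(alpha_attack) == 1,
            is.numeric(alpha_release), length(alpha_release) == 1)
  if (!is.finite(alpha_attack) || alpha_attack < 0 || alpha_attack > 1) {
    stop("`alpha_attack` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.finite(alpha_release) || alpha_release < 0 || alpha_release > 1) {
    stop("`alpha_release` must lie in [0, 1].", call. = FALSE)
  }
  if (alpha_attack > alpha_release) {
    stop("`alpha_attack` must not exceed `alpha_release`: ",
         "the attack direction must respond at least as fast as the release.",
         call. = FALSE)
  }
  structure(list(alpha_attack = alpha_attack, alpha_release = alpha_release),
            class = "tracker_coefficients")
}

#' Analytic calibration of the release coefficient
#'
#' Solves for the release coefficient that makes the envelope-ratio noncycling
#' trigger (`v_high / v_low < r_min`) and the time-since-last-peak trigger
#' (`T_high > T_max`) fire at the same elapsed time on a step drop from PIP to
#' a constant PEEP, for a ventilator with nominal PIP-to-PEEP ratio `r_nom`:
#' `alpha_release = ((r_min - 1) / (r_nom - 1))^(1 / (t_max * fs))`.
#'
#' @param r_min Envelope-ratio alarm threshold, unitless, strictly between 1
#'   and `r_nom`.
#' @param r_nom Nominal PIP-to-PEEP ratio of the ventilator, unitless
#'   (about 2.4 for the pneumatic devices this targets).
#' @param t_max Noncycling alarm time in seconds (converted to samples
#'   internally via `fs`).
#' @param fs Sample rate in samples/s.
#'
#' @return The release coefficient, a number in `(0, 1)`.
#' @seealso [closed_form_release()] for the decay law this inverts.
#' @examples
#' release_coefficient(1.5, 2.4, 15, 100)
#' @export
release_coefficient <- function(r_min = 1.5, r_nom = 2.4, t_max = 15, fs = 100) {
  stopifnot(is.numeric(r_min), is.numeric(r_nom), is.numeric(t_max),
            is.numeric(fs), fs > 0)
  if (!is.finite(r_min) || r_min <= 1) {
    stop("`r_min` must be > 1 (ordering 1 < r_min < r_nom violated).",
         call. = FALSE)
  }
  if (!is.finite(r_nom) || r_min >= r_nom) {
    stop("`r_min` must be < `r_nom` (ordering 1 < r_min < r_nom violated).",
         call. = FALSE)
  }
  t_max_samples <- t_max * fs
  if (t_max_samples < 1) stop("`t_max * fs` must be at least 1 sample.", call. = FALSE)
  ((r_min - 1) / (r_nom - 1))^(1 / t_max_samples)
}

#' 1/e memory of a recursive averager
#'
#' For a one-pole recursive average `y[t] = alpha * y[t-1] + (1 - alpha) * x[t]`
#' the contribution of a past sample decays as `alpha^k`; the time for it to
#' fall to 1/e is `-1 / (fs * log(alpha))` seconds.
#'
#' @param alpha Feedback coefficient, strictly between 0 and 1.
#' @param fs Sample rate in samples/s.
#' @return Time constant in seconds.
#' @examples
#' attack_time_constant(0.9, 100) # ~0.095 s
#' @export
attack_time_constant <- function(alpha, fs) {
  stopifnot(is.numeric(alpha), is.numeric(fs), fs > 0)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly in (0, 1): 0 has no memory, 1 never decays.",
         call. = FALSE)
  }
  -1 / (fs * log(alpha))
}

#' Closed-form envelope release under constant input
#'
#' Under a constant input `floor`, an envelope in release mode decays
#' geometrically: `v[t] = floor + alpha_release^t * (start - floor)`. This is
#' the analytic oracle for [update_envelope()] run repeatedly on a constant
#' signal, and the decay law from which [release_coefficient()] is derived.
#'
#' @param t_elapsed Elapsed time in samples (vectorised, each `>= 0`).
#' @param start Envelope value at `t_elapsed = 0`, cm H2O.
#' @param floor Constant input the envelope decays toward, cm H2O.
#' @param alpha_release Release coefficient in `[0, 1]`.
#' @return Envelope value(s) in cm H2O.
#' @examples
#' a <- release_coefficient(1.5, 2.4, 15, 100)
#' closed_form_release(1500, start = 24, floor = 10, a) # 1.5 * PEEP
#' @export
closed_form_release <- function(t_elapsed, start, floor, alpha_release) {
  stopifnot(all(t_elapsed >= 0))
  floor + alpha_release^t_elapsed * (start - floor)
}

#' Construct the state of one envelope tracker
#'
#' @param direction `"high"` to track the top of the signal, `"low"` for the
#'   bottom.
#' @param value Initial envelope value in cm H2O, conventionally the first
#'   observed pressure sample.
#'
#' @return An object of class `envelope_state`: a list with `direction`,
#'   `value`, `last_attack_value` (the raw pressure at the most recent attack
#'   sample) and `samples_since_attack` (0 immediately after an attack).
#'   Initialisation counts as an attack on the initial value.
#' @examples
#' envelope_state("high", 10)
#' @export
envelope_state <- function(direction = c("high", "low"), value) {
  direction <- match.arg(direction)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    stop("`value` must be a single finite pressure in cm H2O.", call. = FALSE)
  }
  structure(list(direction = direction,
                 value = value,
                 last_attack_value = value,
                 samples_since_attack = 0L),
            class = "envelope_state")
}

#' Advance an envelope tracker by one pressure sample
#'
#' The high tracker takes its attack branch when `p >= value` (ties attack) and
#' its release branch otherwise; the low tracker mirrors the comparisons. The
#' attack branch averages with `alpha_attack`, records `p` as
#' `last_attack_value` and resets `samples_since_attack`; the release branch
#' averages with `alpha_release` and increments the counter.
#'
#' @param state An [envelope_state()].
#' @param p Pressure sample in cm H2O; must be finite.
#' @param coeffs A [tracker_coefficients()] pair.
#'
#' @return A list with elements `state` (the updated `envelope_state`) and
#'   `attacked` (`TRUE` if the attack branch was taken).
#' @examples
#' s <- envelope_state("high", 10)
#' update_envelope(s, 20, tracker_coefficients())$state$value # 11
#' @export
update_envelope <- function(state, p, coeffs = tracker_coefficients()) {
  stopifnot(inherits(state, "envelope_state"),
            inherits(coeffs, "tracker_coefficients"))
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p)) {
    stop("Signal-quality error: pressure sample is not a finite number.",
         call. = FALSE)
  }
  attacked <- if (state$direction == "high") p >= state$value else p <= state$value
  alpha <- if (attacked) coeffs$alpha_attack else coeffs$alpha_release
  state$value <- alpha * state$value + (1 - alpha) * p
  if (attacked) {
    state$last_attack_value <- p
    state$samples_since_attack <- 0L
  } else {
    state$samples_since_attack <- state$samples_since_attack + 1L
  }
  list(state = state, attacked = attacked)
}

#' @export
print.envelope_state <- function(x, ...) {
  cat(sprintf("<envelope_state %s> value=%.4g cm H2O, last attack=%.4g, %d sample(s) since attack\n",
              x$direction, x$value, x$last_attack_value, x$samples_since_attack))
  invisible(x)
}

#' @export
print.tracker_coefficients <- function(x, ...) {
  cat(sprintf("<tracker_coefficients> attack=%.4g, release=%.7g\n",
              x$alpha_attack, x$alpha_release))
  invisible(x)
}
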