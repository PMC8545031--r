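# Single-pass breath monitor: both envelope trackers, the inhale/exhale state
# machine driven by attack events, and once-per-breath smoothed PIP/PEEP/RR
# estimates. The whole state is two envelope values, two breath-cycle extrema,
# three integer counters and the three smoothed metrics.

#' Monitor configuration
#'
#' @param fs Sample rate of the pressure signal in samples/s.
#' @param coefficients A [tracker_coefficients()] pair shared by both envelope
#'   trackers; by default the release coefficient is calibrated for `fs` with
#'   [release_coefficient()].
#' @param alpha_smooth Smoothing coefficient for the once-per-breath PIP, PEEP
#'   and period updates, in `[0, 1)`. 0 keeps no memory; the default 0.5
#'   halves the contribution of each past breath.
#' @param display_resolution_pressure Display rounding step for pressures,
#'   cm H2O (default 1).
#' @param display_resolution_rr Display rounding step for respiratory rate,
#'   breaths/min (default 1).
#'
#' @return An object of class `monitor_config`.
#' @examples
#' monitor_config(fs = 100)
#' @export
monitor_config <- function(fs = 100,
                           coefficients = tracker_coefficients(fs = fs),
                           alpha_smooth = 0.5,
                           display_resolution_pressure = 1,
                           display_resolution_rr = 1) {
  stopifnot(is.numeric(fs), length(fs) == 1, is.finite(fs))
  if (fs <= 0) stop("`fs` must be positive.", call. = FALSE)
  if (!is.numeric(alpha_smooth) || alpha_smooth < 0 || alpha_smooth >= 1) {
    stop("`alpha_smooth` must lie in [0, 1).", call. = FALSE)
  }
  stopifnot(inherits(coefficients, "tracker_coefficients"),
            display_resolution_pressure > 0, display_resolution_rr > 0)
  structure(list(fs = fs,
                 coefficients = coefficients,
                 alpha_smooth = alpha_smooth,
                 display_resolution_pressure = display_resolution_pressure,
                 display_resolution_rr = display_resolution_rr),
            class = "monitor_config")
}

#' @export
print.monitor_config <- function(x, ...) {
  cat(sprintf(paste0("<monitor_config> fs=%g samples/s, alpha_attack=%.4g, ",
                     "alpha_release=%.7g, alpha_smooth=%.3g\n"),
              x$fs, x$coefficients$alpha_attack, x$coefficients$alpha_release,
              x$alpha_smooth))
  invisible(x)
}

#' Initialise the monitor state from the first pressure sample
#'
#' Both envelope trackers start at the first observed pressure (so no spurious
#' attack fires at startup) and the breath state starts as exhaling, so the
#' first rising edge registers as a transition to inhalation. All metrics are
#' invalid until a full breath cycle (two successive high-pressure peaks) has
#' been observed.
#'
#' @param config A [monitor_config()].
#' @param first_pressure First pressure sample, cm H2O (finite).
#' @return An object of class `monitor_state`.
#' @examples
#' init_monitor(monitor_config(), 10)
#' @export
init_monitor <- function(config, first_pressure) {
  stopifnot(inherits(config, "monitor_config"))
  if (!is.numeric(first_pressure) || length(first_pressure) != 1 ||
      !is.finite(first_pressure)) {
    stop("Signal-quality error: first pressure sample is not a finite number.",
         call. = FALSE)
  }
  structure(list(
    high = envelope_state("high", first_pressure),
    low = envelope_state("low", first_pressure),
    breath_state = "exhaling",
    t_peak = 0L,
    sample_index = 1L,
    metrics = list(pip = NA_real_, peep = NA_real_, rr = NA_real_,
                   smoothed_period = NA_real_, breath_count = 0L,
                   n_cycle_ends = 0L, valid = FALSE)
  ), class = "monitor_state")
}

#' @export
print.monitor_state <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<monitor_state> sample %d, %s; v_high=%.4g, v_low=%.4g\n",
              x$sample_index, x$breath_state, x$high$value, x$low$value))
  cat(sprintf("  breaths=%d, PIP=%s, PEEP=%s, RR=%s (%s)\n",
              m$breath_count,
              format(m$pip, digits = 4), format(m$peep, digits = 4),
              format(m$rr, digits = 4),
              if (m$valid) "valid" else "warming up"))
  invisible(x)
}

#' Exponentially smooth a per-breath metric
#'
#' One step of the recursive smoother `alpha * prev + (1 - alpha) * new`;
#' the contribution of an update decays geometrically with each later update.
#'
#' @param prev Previous smoothed value.
#' @param new New measurement.
#' @param alpha_smooth Smoothing coefficient in `[0, 1)`.
#' @return The updated smoothed value.
#' @examples
#' exponential_smooth(30, 34, 0.5) # 32
#' @export
exponential_smooth <- function(prev, new, alpha_smooth) {
  if (!is.numeric(alpha_smooth) || alpha_smooth < 0 || alpha_smooth >= 1) {
    stop("`alpha_smooth` must lie in [0, 1).", call. = FALSE)
  }
  alpha_smooth * prev + (1 - alpha_smooth) * new
}

#' Respiratory rate from a smoothed breath period
#'
#' @param smoothed_period Breath period in samples (positive).
#' @param fs Sample rate in samples/s.
#' @return Respiratory rate in breaths/min: `60 * fs / smoothed_period`.
#' @examples
#' respiratory_rate(150, 100) # 40 breaths/min
#' @export
respiratory_rate <- function(smoothed_period, fs) {
  stopifnot(is.numeric(smoothed_period), is.numeric(fs), fs > 0)
  if (any(smoothed_period <= 0)) {
    stop("`smoothed_period` must be positive.", call. = FALSE)
  }
  60 * fs / smoothed_period
}

#' Advance the monitor by one pressure sample
#'
#' Updates both envelope trackers, the inhale/exhale state machine and the
#' smoothed metrics. The high tracker is evaluated before the low tracker. A
#' breath-state transition requires a strict attack (`p > v_high` or
#' `p < v_low`): the first attack of a genuine attack run is always strict,
#' while tie attacks (which keep the envelope arithmetic exact on plateaus)
#' never toggle the state, so a constant signal produces no breaths.
#'
#' On the transition to inhalation the PEEP estimate is updated with the last
#' low-pressure attack value; on the transition to exhalation the PIP estimate
#' is updated with the last high-pressure attack value, the breath period
#' (interval between the two most recent high-pressure peaks) is smoothed, and
#' the respiratory rate is recomputed. The first completed measurement of each
#' metric initialises its smoothed value directly; the first peak-to-peak
#' interval after startup is discarded because the monitor may have started
#' mid-breath.
#'
#' @param state A [monitor_state][init_monitor()].
#' @param p Next pressure sample, cm H2O.
#' @param config The [monitor_config()] used at initialisation.
#' @return A list with `state` (updated) and `transition` (`NA`, `"to_inhale"`
#'   or `"to_exhale"`).
#' @examples
#' st <- init_monitor(monitor_config(), 10)
#' monitor_step(st, 12, monitor_config())$transition # "to_inhale"
#' @export
monitor_step <- function(state, p, config) {
  stopifnot(inherits(state, "monitor_state"), inherits(config, "monitor_config"))
  aS <- config$alpha_smooth
  m <- state$metrics
  transition <- NA_character_

  state$t_peak <- state$t_peak + 1L
  state$sample_index <- state$sample_index + 1L

  # High-pressure tracker first, as in the single-pass loop.
  strict_high <- is.finite(p) && p > state$high$value
  up <- update_envelope(state$high, p, config$coefficients)
  state$high <- up$state
  if (up$attacked && strict_high && state$breath_state == "exhaling") {
    state$breath_state <- "inhaling"
    transition <- "to_inhale"
    m$peep <- if (is.na(m$peep)) state$low$last_attack_value else
      exponential_smooth(m$peep, state$low$last_attack_value, aS)
  }

  strict_low <- p < state$low$value
  lo <- update_envelope(state$low, p, config$coefficients)
  state$low <- lo$state
  if (lo$attacked && strict_low && state$breath_state == "inhaling" &&
      is.na(transition)) {
    state$breath_state <- "exhaling"
    transition <- "to_exhale"
    m$pip <- if (is.na(m$pip)) state$high$last_attack_value else
      exponential_smooth(m$pip, state$high$last_attack_value, aS)
    interval <- state$t_peak - state$high$samples_since_attack
    m$n_cycle_ends <- m$n_cycle_ends + 1L
    if (m$n_cycle_ends > 1L) {
      m$smoothed_period <- if (is.na(m$smoothed_period)) interval else
        exponential_smooth(m$smoothed_period, interval, aS)
      m$rr <- respiratory_rate(m$smoothed_period, config$fs)
    }
    state$t_peak <- state$high$samples_since_attack
    m$breath_count <- m$breath_count + 1L
  }

  m$valid <- !is.na(m$pip) && !is.na(m$peep) && !is.na(m$smoothed_period)
  state$metrics <- m
  list(state = state, transition = transition)
}

#' Run the breath monitor over a full pressure trace
#'
#' Batch driver over the single-pass update: initialises the monitor from the
#' first sample and advances it through the rest of the series. The result is
#' deterministic given the input.
#'
#' @param x The pressure trace: a data frame with a `pressure` column (and
#'   optionally a `time` column in seconds, from which the sample rate is
#'   inferred), a bare numeric vector, or a simulated waveform from
#'   [generate_waveform()].
#' @param config A [monitor_config()]; by default one is built at the sample
#'   rate carried by (or inferred from) `x`, falling back to 100 samples/s for
#'   a bare vector.
#'
#' @return An object of class `vent_monitor`: a list with
#' \describe{
#'   \item{samples}{per-sample tibble: `sample`, `time`, `pressure`, `v_high`,
#'     `v_low`, `t_high`, `t_low`, `t_peak`, `breath_state`, `transition`,
#'     `pip`, `peep`, `rr` (all unrounded; `NA` until first measured), `valid`,
#'     `breath_count`.}
#'   \item{breaths}{per-breath tibble (one row per completed inhale-to-exhale
#'     transition): smoothed `pip`, `peep`, `rr`, `period_samples`, plus
#'     display-rounded `pip_disp`, `peep_disp`, `rr_disp`.}
#'   \item{transitions}{tibble of breath-state transitions.}
#'   \item{config}{the configuration used.}
#' }
#' Use [tidy()] for the per-breath table, [glance()] for a one-row summary and
#' [ggplot2::autoplot()] to plot the trace with its envelopes.
#' @examples
#' sim <- generate_waveform(waveform_spec(duration = 30))
#' fit <- run_monitor(sim)
#' glance(fit)
#' @export
run_monitor <- function(x, config = NULL) {
  tr <- as_pressure_input(x)
  if (is.null(config)) {
    config <- monitor_config(fs = if (is.na(tr$fs)) 100 else tr$fs)
  }
  stopifnot(inherits(config, "monitor_config"))
  if (!is.na(tr$fs) && abs(tr$fs - config$fs) > 1e-9 * tr$fs) {
    stop(sprintf("Trace sample rate (%g) does not match config fs (%g).",
                 tr$fs, config$fs), call. = FALSE)
  }
  p <- tr$pressure
  n <- length(p)
  if (n == 0) stop("Pressure series is empty.", call. = FALSE)
  bad <- which(!is.finite(p))
  if (length(bad) > 0) {
    stop(sprintf("Signal-quality error: non-finite pressure at sample %d.",
                 bad[1]), call. = FALSE)
  }

  fs <- config$fs
  aA <- config$coefficients$alpha_attack
  aR <- config$coefficients$alpha_release
  aS <- config$alpha_smooth

  # Scalar state (tight loop; monitor_step() is the reference implementation
  # and the two are asserted equivalent in the test suite).
  vh <- vl <- p[1]
  Vh <- Vl <- p[1]
  Th <- Tl <- 0L
  Tpk <- 0L
  inhaling <- FALSE
  pip <- peep <- period <- rr <- NA_real_
  bc <- 0L
  nie <- 0L

  v_high <- v_low <- pip_v <- peep_v <- rr_v <- numeric(n)
  t_high <- t_low <- t_peak <- integer(n)
  bstate <- character(n)
  trans <- rep(NA_character_, n)
  valid_v <- logical(n)
  bcount <- integer(n)

  br_sample <- integer(0); br_pip <- br_peep <- br_rr <- br_period <- numeric(0)

  v_high[1] <- vh; v_low[1] <- vl
  t_high[1] <- Th; t_low[1] <- Tl; t_peak[1] <- Tpk
  bstate[1] <- "exhaling"
  pip_v[1] <- pip; peep_v[1] <- peep; rr_v[1] <- rr
  valid_v[1] <- FALSE; bcount[1] <- bc

  if (n >= 2) for (i in 2:n) {
    pi <- p[i]
    Tpk <- Tpk + 1L
    transition <- NA_character_

    if (pi >= vh) {
      strict <- pi > vh
      vh <- aA * vh + (1 - aA) * pi
      Vh <- pi
      Th <- 0L
      if (strict && !inhaling) {
        inhaling <- TRUE
        transition <- "to_inhale"
        peep <- if (is.na(peep)) Vl else aS * peep + (1 - aS) * Vl
      }
    } else {
      vh <- aR * vh + (1 - aR) * pi
      Th <- Th + 1L
    }

    if (pi <= vl) {
      strict <- pi < vl
      vl <- aA * vl + (1 - aA) * pi
      Vl <- pi
      Tl <- 0L
      if (strict && inhaling && is.na(transition)) {
        inhaling <- FALSE
        transition <- "to_exhale"
        pip <- if (is.na(pip)) Vh else aS * pip + (1 - aS) * Vh
        interval <- Tpk - Th
        nie <- nie + 1L
        if (nie > 1L) {
          period <- if (is.na(period)) interval else
            aS * period + (1 - aS) * interval
          rr <- 60 * fs / period
        }
        Tpk <- Th
        bc <- bc + 1L
        br_sample <- c(br_sample, i)
        br_pip <- c(br_pip, pip); br_peep <- c(br_peep, peep)
        br_rr <- c(br_rr, rr); br_period <- c(br_period, period)
      }
    } else {
      vl <- aR * vl + (1 - aR) * pi
      Tl <- Tl + 1L
    }

    v_high[i] <- vh; v_low[i] <- vl
    t_high[i] <- Th; t_low[i] <- Tl; t_peak[i] <- Tpk
    bstate[i] <- if (inhaling) "inhaling" else "exhaling"
    trans[i] <- transition
    pip_v[i] <- pip; peep_v[i] <- peep; rr_v[i] <- rr
    valid_v[i] <- !is.na(pip) && !is.na(peep) && !is.na(period)
    bcount[i] <- bc
  }

  time <- (seq_len(n) - 1) / fs
  samples <- tibble::tibble(
    sample = seq_len(n), time = time, pressure = p,
    v_high = v_high, v_low = v_low,
    t_high = t_high, t_low = t_low, t_peak = t_peak,
    breath_state = bstate, transition = trans,
    pip = pip_v, peep = peep_v, rr = rr_v,
    valid = valid_v, breath_count = bcount
  )

  round_to <- function(x, res) round(x / res) * res
  breaths <- tibble::tibble(
    breath = seq_along(br_sample),
    sample = br_sample,
    time = (br_sample - 1) / fs,
    pip = br_pip, peep = br_peep, rr = br_rr, period_samples = br_period,
    pip_disp = round_to(br_pip, config$display_resolution_pressure),
    peep_disp = round_to(br_peep, config$display_resolution_pressure),
    rr_disp = round_to(br_rr, config$display_resolution_rr)
  )

  tr_idx <- which(!is.na(trans))
  transitions <- tibble::tibble(
    sample = tr_idx, time = (tr_idx - 1) / fs, type = trans[tr_idx]
  )

  structure(list(samples = samples, breaths = breaths,
                 transitions = transitions, config = config),
            class = "vent_monitor")
}

# Normalise the accepted input shapes to list(pressure=, fs= [NA if unknown]).
as_pressure_input <- function(x) {
  if (inherits(x, "vent_sim")) {
    return(list(pressure = x$trace$pressure, fs = x$spec$fs))
  }
  if (inherits(x, "pressure_trace")) {
    return(list(pressure = x$samples, fs = x$fs))
  }
  if (is.data.frame(x)) {
    if (!"pressure" %in% names(x)) {
      stop("Data frame input must have a `pressure` column.", call. = FALSE)
    }
    fs <- NA_real_
    if ("time" %in% names(x) && nrow(x) >= 2) {
      fs <- 1 / stats::median(diff(x$time))
    }
    return(list(pressure = as.numeric(x$pressure), fs = fs))
  }
  if (is.numeric(x)) return(list(pressure = as.numeric(x), fs = NA_real_))
  stop("Unsupported pressure input; supply a data frame, numeric vector, ",
       "pressure_trace or simulated waveform.", call. = FALSE)
}

#' @export
print.vent_monitor <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<vent_monitor> %d samples at %g samples/s (%.1f s), %d breath(s)\n",
              g$n_samples, x$config$fs, g$duration, g$n_breaths))
  if (g$valid) {
    cat(sprintf("  PIP %.1f cm H2O, PEEP %.1f cm H2O, RR %.1f breaths/min\n",
                g$pip, g$peep, g$rr))
  } else {
    cat("  metrics not yet valid (no complete breath cycle observed)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-breath estimates from a monitor run
#'
#' @param x A `vent_monitor` from [run_monitor()].
#' @param ... Unused.
#' @return The per-breath tibble (one row per completed breath) with smoothed
#'   and display-rounded PIP, PEEP and RR.
#' @export
tidy.vent_monitor <- function(x, ...) x$breaths

#' One-row summary of a monitor run
#'
#' @param x A `vent_monitor` from [run_monitor()].
#' @param ... Unused.
#' @return A one-row tibble with the final smoothed metrics.
#' @export
glance.vent_monitor <- function(x, ...) {
  s <- x$samples[nrow(x$samples), ]
  tibble::tibble(n_samples = nrow(x$samples),
                 duration = s$time,
                 n_breaths = nrow(x$breaths),
                 pip = s$pip, peep = s$peep, rr = s$rr,
                 valid = s$valid)
}

#' Plot a monitor run: pressure, envelopes and breath transitions
#'
#' @param object A `vent_monitor` from [run_monitor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vent_monitor <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$samples[, c("time", "pressure", "v_high", "v_low")],
    -"time", names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$transitions,
                        ggplot2::aes(xintercept = .data$time),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "pressure (cm H2O)", colour = NULL)
}
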