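# Ground-truth-annotated synthetic pressure-cycled ventilator waveforms.
# The base waveform rises exponentially from PEEP to PIP during inspiration
# and decays exponentially from PIP to PEEP during expiration, switching phase
# exactly at the threshold crossings (the pressure-switching mechanism of a
# pneumatic ventilator, without a lung-mechanics model). Scheduled events
# overlay the failure scenarios used to exercise the alarm engine.

#' Specification of a synthetic ventilator waveform
#'
#' @param pip_set Set peak inspiratory pressure, cm H2O.
#' @param peep_set Set positive end-expiratory pressure, cm H2O; defaults to
#'   `pip_set / r_nom`, the fixed mechanical PIP-to-PEEP ratio of a
#'   pressure-cycled device.
#' @param rr_set Set respiratory rate, breaths/min. The cycle period is
#'   exactly `60 / rr_set` seconds.
#' @param inspiratory_fraction Fraction of the cycle spent in inspiration,
#'   in (0, 1); about 1/3 for these devices.
#' @param tau_insp,tau_exp Time constants (s) of the exponential approach
#'   during inspiration and expiration. The approach targets are solved so the
#'   noiseless trace reaches `pip_set` exactly at end-inspiration and
#'   `peep_set` exactly at end-expiration.
#' @param fs Sample rate, samples/s.
#' @param duration Record length, seconds.
#' @param noise_sd Standard deviation of additive white Gaussian sensor noise,
#'   cm H2O (0 for a noiseless trace).
#' @param seed Integer seed making the noise reproducible.
#' @param r_nom Nominal PIP-to-PEEP ratio used for the `peep_set` default.
#' @param events List of scheduled [sim_event()]s.
#'
#' @return An object of class `waveform_spec`.
#' @examples
#' waveform_spec(pip_set = 24, rr_set = 20, duration = 60)
#' @export
waveform_spec <- function(pip_set = 24, peep_set = pip_set / r_nom,
                          rr_set = 20, inspiratory_fraction = 1 / 3,
                          tau_insp = 0.3, tau_exp = 0.8,
                          fs = 100, duration = 60,
                          noise_sd = 0, seed = 1L,
                          r_nom = 2.4, events = list()) {
  bad <- function(msg) stop(msg, call. = FALSE)
  if (!is.numeric(pip_set) || !is.finite(pip_set) || pip_set <= 0) {
    bad("`pip_set` must be a positive pressure in cm H2O.")
  }
  if (!is.numeric(peep_set) || peep_set <= 0) bad("`peep_set` must be positive.")
  if (peep_set >= pip_set) bad("`peep_set` must be below `pip_set`.")
  if (!is.numeric(rr_set) || rr_set <= 0) bad("`rr_set` must be positive.")
  if (inspiratory_fraction <= 0 || inspiratory_fraction >= 1) {
    bad("`inspiratory_fraction` must lie strictly in (0, 1).")
  }
  if (tau_insp <= 0 || tau_exp <= 0) bad("`tau_insp` and `tau_exp` must be positive.")
  if (fs <= 0) bad("`fs` must be positive.")
  if (duration <= 0) bad("`duration` must be positive.")
  if (noise_sd < 0) bad("`noise_sd` must be nonnegative.")
  for (ev in events) {
    if (!inherits(ev, "sim_event")) bad("`events` must be a list of sim_event objects.")
    if (ev$start < 0 || ev$start > duration) {
      bad(sprintf("event `%s` start %g s outside [0, %g].", ev$kind, ev$start, duration))
    }
  }
  structure(list(pip_set = pip_set, peep_set = peep_set, rr_set = rr_set,
                 inspiratory_fraction = inspiratory_fraction,
                 tau_insp = tau_insp, tau_exp = tau_exp,
                 fs = fs, duration = duration, noise_sd = noise_sd,
                 seed = as.integer(seed), r_nom = r_nom, events = events),
            class = "waveform_spec")
}

#' Scheduled simulator event
#'
#' Overlays a failure or patient-activity scenario on the base waveform from
#' its start time onward.
#'
#' @param kind One of:
#'   \describe{
#'     \item{`disconnect_atmosphere`}{circuit fully open: pressure drops to
#'       atmospheric (0 cm H2O).}
#'     \item{`disconnect_partial`}{cycling stops and the pressure holds at
#'       `hold` (default `peep_set`).}
#'     \item{`obstruction_high`}{a momentary dip to `dip` cm H2O for
#'       `dip_duration` s, then constant high pressure `hold`
#'       (default `pip_set`).}
#'     \item{`dial_change`}{the PIP dial is turned to `new_pip`; PEEP follows
#'       the mechanical ratio. Ramped over one cycle by default
#'       (`ramp = TRUE`); `ramp = FALSE` steps instantaneously.}
#'     \item{`spontaneous_breath`}{the patient pulls pressure below PEEP: a
#'       half-sine dip of `depth` cm H2O lasting `duration` s, floored at
#'       0 cm H2O.}
#'     \item{`small_oscillation`}{cycling is replaced by a low-amplitude
#'       sinusoid: `level + amplitude * sin(2 pi freq t)`.}
#'   }
#' @param start Event start time, seconds.
#' @param ... Kind-specific parameters (see above).
#' @return An object of class `sim_event`.
#' @examples
#' sim_event("disconnect_atmosphere", start = 30)
#' sim_event("dial_change", start = 30, new_pip = 18, ramp = FALSE)
#' @export
sim_event <- function(kind = c("disconnect_atmosphere", "disconnect_partial",
                               "obstruction_high", "dial_change",
                               "spontaneous_breath", "small_oscillation"),
                      start, ...) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(start), length(start) == 1, start >= 0)
  structure(list(kind = kind, start = start, params = list(...)),
            class = "sim_event")
}

# TRUE for events after which normal cycling no longer happens.
stops_cycling <- function(kind) {
  kind %in% c("disconnect_atmosphere", "disconnect_partial",
              "obstruction_high", "small_oscillation")
}

#' Generate an annotated synthetic ventilator waveform
#'
#' Deterministic given the spec (including its seed). The noiseless base
#' waveform touches `pip_set` exactly at end-inspiration and `peep_set`
#' exactly at end-expiration of every cycle, with cycle period
#' `60 / rr_set` s. Scheduled events override the base dynamics from their
#' start time.
#'
#' @param spec A [waveform_spec()].
#' @return An object of class `vent_sim`: a list with
#'   \describe{
#'     \item{trace}{tibble with `time` (s) and `pressure` (cm H2O).}
#'     \item{truth}{per-breath ground truth for cycles unaffected by
#'       cycling-stopping events: `cycle`, `t_start`, `t_peak`, `pip`, `peep`,
#'       `period`.}
#'     \item{event_windows}{tibble of scheduled events (`kind`, `start`,
#'       `end`).}
#'     \item{spec}{the generating spec.}
#'   }
#' @examples
#' sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
#'                                        rr_set = 20, duration = 60))
#' nrow(sim$truth) # 20 cycles
#' @export
generate_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  fs <- spec$fs
  n <- round(spec$duration * fs)
  time <- (seq_len(n) - 1) / fs
  period <- 60 / spec$rr_set
  t_insp <- spec$inspiratory_fraction * period
  t_exp <- period - t_insp
  ratio <- spec$pip_set / spec$peep_set

  # PIP trajectory (dial_change events); PEEP follows the mechanical ratio.
  pip_t <- rep(spec$pip_set, n)
  for (ev in spec$events) {
    if (ev$kind != "dial_change") next
    new_pip <- ev$params$new_pip %||% spec$pip_set
    ramp <- ev$params$ramp %||% TRUE
    if (ramp) {
      frac <- pmin(pmax((time - ev$start) / period, 0), 1)
    } else {
      frac <- as.numeric(time >= ev$start)
    }
    pip_t <- pip_t + frac * (new_pip - pip_t)
  }
  peep_t <- pip_t / ratio

  phase <- time %% period
  cyc <- floor(time / period)
  # Solve the exponential approach so the phase endpoints are met exactly.
  ei <- exp(-t_insp / spec$tau_insp)
  ee <- exp(-t_exp / spec$tau_exp)
  target <- (pip_t - peep_t * ei) / (1 - ei)   # slightly above PIP
  floor_p <- (peep_t - pip_t * ee) / (1 - ee)  # slightly below PEEP
  insp <- phase < t_insp
  pressure <- ifelse(
    insp,
    target - (target - peep_t) * exp(-phase / spec$tau_insp),
    floor_p + (pip_t - floor_p) * exp(-(phase - t_insp) / spec$tau_exp)
  )

  # Overriding events.
  stop_start <- Inf
  for (ev in spec$events) {
    after <- time >= ev$start
    prm <- ev$params
    switch(ev$kind,
      disconnect_atmosphere = {
        pressure[after] <- 0
        stop_start <- min(stop_start, ev$start)
      },
      disconnect_partial = {
        pressure[after] <- prm$hold %||% spec$peep_set
        stop_start <- min(stop_start, ev$start)
      },
      obstruction_high = {
        dip <- prm$dip %||% 2
        dip_dur <- prm$dip_duration %||% 0.5
        hold <- prm$hold %||% spec$pip_set
        pressure[after] <- hold
        pressure[after & time < ev$start + dip_dur] <- dip
        stop_start <- min(stop_start, ev$start)
      },
      small_oscillation = {
        level <- prm$level %||% spec$peep_set
        amplitude <- prm$amplitude %||% 1
        freq <- prm$freq %||% (spec$rr_set / 60)
        tt <- time[after] - ev$start
        pressure[after] <- level + amplitude * sin(2 * pi * freq * tt)
        stop_start <- min(stop_start, ev$start)
      },
      spontaneous_breath = {
        depth <- prm$depth %||% spec$peep_set
        dur <- prm$duration %||% 1.5
        win <- after & time < ev$start + dur
        dip <- depth * sin(pi * (time[win] - ev$start) / dur)
        pressure[win] <- pmax(pressure[win] - dip, 0)
      },
      dial_change = NULL
    )
  }

  if (spec$noise_sd > 0) {
    pressure <- pressure + withr::with_seed(
      spec$seed, stats::rnorm(n, sd = spec$noise_sd))
  }

  # Ground truth for cycles that complete before any cycling-stopping event.
  n_cycles <- floor(spec$duration / period + 1e-9)
  k <- seq_len(n_cycles) - 1
  t_start <- k * period
  complete <- (t_start + period) <= min(stop_start, spec$duration) + 1e-9
  k <- k[complete]
  t_start <- t_start[complete]
  t_pk <- t_start + t_insp
  idx_pk <- pmin(pmax(round(t_pk * fs) + 1, 1), n)
  idx_st <- pmin(round(t_start * fs) + 1, n)
  truth <- tibble::tibble(
    cycle = k + 1L,
    t_start = t_start,
    t_peak = t_pk,
    pip = pip_t[idx_pk],
    peep = peep_t[idx_st],
    period = period
  )

  event_windows <- if (length(spec$events) > 0) {
    tibble::tibble(
      kind = vapply(spec$events, `[[`, character(1), "kind"),
      start = vapply(spec$events, `[[`, numeric(1), "start"),
      end = vapply(spec$events, function(ev) {
        if (ev$kind == "spontaneous_breath") {
          min(ev$start + (ev$params$duration %||% 1.5), spec$duration)
        } else if (ev$kind == "dial_change") {
          min(ev$start + period, spec$duration)
        } else spec$duration
      }, numeric(1))
    )
  } else {
    tibble::tibble(kind = character(0), start = numeric(0), end = numeric(0))
  }

  structure(list(trace = tibble::tibble(time = time, pressure = pressure),
                 truth = truth, event_windows = event_windows, spec = spec),
            class = "vent_sim")
}

#' Decimate a simulated trace to a lower sample rate
#'
#' Keeps every `factor`-th sample starting from the first; the sample rate is
#' divided by `factor`. Ground-truth annotations are in seconds and carry over
#' unchanged.
#'
#' @param trace A `vent_sim` from [generate_waveform()], or a data frame with
#'   `time` and `pressure` columns.
#' @param factor Positive integer decimation factor; 1 is the identity.
#' @return The decimated object, same class as the input.
#' @examples
#' sim <- generate_waveform(waveform_spec(duration = 10))
#' decimate_trace(sim, 10)$spec$fs # 10
#' @export
decimate_trace <- function(trace, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a positive integer.", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (inherits(trace, "vent_sim")) {
    keep <- seq(1, nrow(trace$trace), by = factor)
    trace$trace <- trace$trace[keep, ]
    trace$spec$fs <- trace$spec$fs / factor
    return(trace)
  }
  if (is.data.frame(trace)) {
    return(trace[seq(1, nrow(trace), by = factor), ])
  }
  stop("`trace` must be a vent_sim or a data frame.", call. = FALSE)
}

#' @export
print.vent_sim <- function(x, ...) {
  cat(sprintf(paste0("<vent_sim> %d samples at %g samples/s (%g s): ",
                     "PIP %g / PEEP %g cm H2O, %g breaths/min, noise sd %g\n"),
              nrow(x$trace), x$spec$fs, x$spec$duration,
              x$spec$pip_set, round(x$spec$peep_set, 3), x$spec$rr_set,
              x$spec$noise_sd))
  if (nrow(x$event_windows) > 0) {
    cat("  events:", paste(sprintf("%s@%gs", x$event_windows$kind,
                                   x$event_windows$start), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as_tibble.vent_sim <- function(x, ...) x$trace

#' Plot a simulated waveform
#'
#' @param object A `vent_sim` from [generate_waveform()].
#' @param ... Unused.
#' @return A ggplot object with event starts marked.
#' @export
autoplot.vent_sim <- function(object, ...) {
  gg <- ggplot2::ggplot(object$trace,
                        ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (cm H2O)")
  if (nrow(object$event_windows) > 0) {
    gg <- gg + ggplot2::geom_vline(data = object$event_windows,
                                   ggplot2::aes(xintercept = .data$start),
                                   linetype = "dashed", colour = "firebrick")
  }
  gg
}
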