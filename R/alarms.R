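# Alarm engine: instantaneous pressure limits, respiratory-rate band, and the
# four-part noncycling detector (time since last high/low attack, envelope
# ratio, envelope difference), with onset/clear event bookkeeping.

#' Alarm thresholds
#'
#' Constructs and validates the tunable alarm settings. Violations of the
#' supported tuning ranges are reported naming the offending range.
#'
#' @param p_max High-pressure limit, cm H2O (`30 <= p_max <= 90`).
#' @param p_min Low-pressure limit, cm H2O (`1 <= p_min <= 20`); set near
#'   atmospheric to catch circuit disconnects.
#' @param rr_max High respiratory-rate limit, breaths/min
#'   (`15 <= rr_max <= 60`).
#' @param rr_min Low respiratory-rate limit, breaths/min (`5 <= rr_min <= 15`).
#' @param t_max Noncycling alarm time in seconds (`5 <= t_max <= 30`): the
#'   longest tolerated gap since the last attack event of either tracker.
#' @param r_min Minimum high-to-low envelope ratio, unitless,
#'   strictly between 1 and `r_nom`.
#' @param d_min Minimum high-minus-low envelope difference, cm H2O (positive).
#' @param r_nom Nominal PIP-to-PEEP ratio of the ventilator, unitless.
#'
#' @return An object of class `alarm_thresholds`.
#' @examples
#' alarm_thresholds()
#' @export
alarm_thresholds <- function(p_max = 40, p_min = 5, rr_max = 40, rr_min = 8,
                             t_max = 15, r_min = 1.5, d_min = 3, r_nom = 2.4) {
  chk <- function(val, lo, hi, name, unit) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) ||
        val < lo || val > hi) {
      stop(sprintf("`%s` = %s outside supported range %g-%g %s.",
                   name, format(val), lo, hi, unit), call. = FALSE)
    }
  }
  chk(p_max, 30, 90, "p_max", "cm H2O")
  chk(p_min, 1, 20, "p_min", "cm H2O")
  chk(rr_max, 15, 60, "rr_max", "breaths/min")
  chk(rr_min, 5, 15, "rr_min", "breaths/min")
  chk(t_max, 5, 30, "t_max", "s")
  if (!is.numeric(r_min) || r_min <= 1 || r_min >= r_nom) {
    stop("`r_min` must satisfy 1 < r_min < r_nom.", call. = FALSE)
  }
  if (!is.numeric(d_min) || d_min <= 0) {
    stop("`d_min` must be a positive pressure difference in cm H2O.",
         call. = FALSE)
  }
  structure(list(p_max = p_max, p_min = p_min, rr_max = rr_max,
                 rr_min = rr_min, t_max = t_max, r_min = r_min,
                 d_min = d_min, r_nom = r_nom),
            class = "alarm_thresholds")
}

#' @export
print.alarm_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<alarm_thresholds> p: %g-%g cm H2O, RR: %g-%g breaths/min, ",
                     "t_max=%g s, r_min=%g, d_min=%g cm H2O (r_nom=%g)\n"),
              x$p_min, x$p_max, x$rr_min, x$rr_max,
              x$t_max, x$r_min, x$d_min, x$r_nom))
  invisible(x)
}

#' Instantaneous pressure and respiratory-rate alarm checks
#'
#' High/low pressure compare the current raw sample against the limits and
#' trigger immediately; high/low respiratory rate compare the unrounded
#' smoothed rate and are inactive until the metrics are valid (one full breath
#' cycle observed).
#'
#' @param p Current pressure sample, cm H2O.
#' @param metrics Metrics list from a [monitor_state][init_monitor()]
#'   (fields `rr` and `valid`), or `NULL` to skip the rate checks.
#' @param thresholds An [alarm_thresholds()].
#' @return Character vector of active alarm kinds, a subset of
#'   `c("high_pressure", "low_pressure", "high_rr", "low_rr")`.
#' @examples
#' check_instant_alarms(95, NULL, alarm_thresholds(p_max = 90))
#' @export
check_instant_alarms <- function(p, metrics = NULL,
                                 thresholds = alarm_thresholds()) {
  stopifnot(inherits(thresholds, "alarm_thresholds"))
  active <- character(0)
  if (p > thresholds$p_max) active <- c(active, "high_pressure")
  if (p < thresholds$p_min) active <- c(active, "low_pressure")
  if (!is.null(metrics) && isTRUE(metrics$valid) && !is.na(metrics$rr)) {
    if (metrics$rr > thresholds$rr_max) active <- c(active, "high_rr")
    if (metrics$rr < thresholds$rr_min) active <- c(active, "low_rr")
  }
  active
}

#' Noncycling alarm check
#'
#' The noncycling alarm fires if ANY of four sub-conditions holds: too many
#' samples since the last high-pressure attack (`time_high`), too many since
#' the last low-pressure attack (`time_low`), envelope ratio below `r_min`
#' (`ratio`), or envelope difference below `d_min` (`difference`). The ratio
#' sub-condition is skipped when the low envelope is below 0.5 cm H2O, where a
#' pressure ratio is meaningless and the low-pressure alarm already covers the
#' failure; assisted breathing can legitimately pull the airway near
#' atmospheric.
#'
#' Callers are expected to apply this only after warm-up (see
#' [detect_alarms()]): at startup both envelopes coincide, so the ratio and
#' difference sub-conditions are uninformative until a full breath cycle has
#' been observed.
#'
#' @param state A [monitor_state][init_monitor()].
#' @param thresholds An [alarm_thresholds()].
#' @param fs Sample rate in samples/s (converts `t_max` to samples).
#' @return A list with `active` (logical) and `sub_conditions` (character
#'   vector among `time_high`, `time_low`, `ratio`, `difference`).
#' @export
check_noncycling <- function(state, thresholds, fs) {
  stopifnot(inherits(state, "monitor_state"),
            inherits(thresholds, "alarm_thresholds"), fs > 0)
  t_max_samples <- thresholds$t_max * fs
  sub <- character(0)
  if (state$high$samples_since_attack > t_max_samples) sub <- c(sub, "time_high")
  if (state$low$samples_since_attack > t_max_samples) sub <- c(sub, "time_low")
  vh <- state$high$value; vl <- state$low$value
  if (vl >= 0.5 && vh / vl < thresholds$r_min) sub <- c(sub, "ratio")
  if (vh - vl < thresholds$d_min) sub <- c(sub, "difference")
  list(active = length(sub) > 0, sub_conditions = sub)
}

#' Evaluate all alarm conditions over a monitor run
#'
#' Applies the instantaneous, respiratory-rate and noncycling checks to every
#' sample of a [run_monitor()] result and collapses the per-sample activity
#' into onset/clear events. Alarms auto-clear when their condition clears
#' (no latching). The ratio and difference noncycling sub-conditions are
#' suppressed during warm-up: until the metrics first become valid or until
#' `t_max` seconds have elapsed since startup, whichever comes first. The two
#' time sub-conditions run from startup (they cannot fire before `t_max`).
#'
#' @param monitor A `vent_monitor` from [run_monitor()].
#' @param thresholds An [alarm_thresholds()].
#' @return An object of class `vent_alarms`: a list with
#'   \describe{
#'     \item{events}{tibble of [alarm events][alarm_timeline()], ordered by
#'       onset, with `onset_time`/`clear_time` in seconds and, for noncycling
#'       events, the `sub_condition` active at onset.}
#'     \item{active}{per-sample tibble of the five alarm kinds plus the four
#'       noncycling sub-conditions, as logical columns.}
#'     \item{thresholds}{the thresholds used.}
#'   }
#' @examples
#' sim <- generate_waveform(waveform_spec(duration = 40,
#'   events = list(sim_event("disconnect_atmosphere", start = 20))))
#' detect_alarms(run_monitor(sim), alarm_thresholds())
#' @export
detect_alarms <- function(monitor, thresholds = alarm_thresholds()) {
  stopifnot(inherits(monitor, "vent_monitor"),
            inherits(thresholds, "alarm_thresholds"))
  s <- monitor$samples
  fs <- monitor$config$fs
  t_max_samples <- thresholds$t_max * fs

  first_valid <- match(TRUE, s$valid)
  warm_end <- min(if (is.na(first_valid)) Inf else first_valid,
                  t_max_samples)
  warmed <- s$sample > warm_end

  nc_time_high <- s$t_high > t_max_samples
  nc_time_low <- s$t_low > t_max_samples
  nc_ratio <- warmed & s$v_low >= 0.5 & (s$v_high / s$v_low < thresholds$r_min)
  nc_diff <- warmed & (s$v_high - s$v_low < thresholds$d_min)

  active <- tibble::tibble(
    sample = s$sample,
    time = s$time,
    high_pressure = s$pressure > thresholds$p_max,
    low_pressure = s$pressure < thresholds$p_min,
    high_rr = s$valid & !is.na(s$rr) & s$rr > thresholds$rr_max,
    low_rr = s$valid & !is.na(s$rr) & s$rr < thresholds$rr_min,
    noncycling = nc_time_high | nc_time_low | nc_ratio | nc_diff,
    nc_time_high = nc_time_high, nc_time_low = nc_time_low,
    nc_ratio = nc_ratio, nc_difference = nc_diff
  )

  events <- alarm_timeline(active[c("high_pressure", "low_pressure",
                                    "high_rr", "low_rr", "noncycling")])
  if (nrow(events) > 0) {
    sub_mat <- as.matrix(active[c("nc_time_high", "nc_time_low",
                                  "nc_ratio", "nc_difference")])
    sub_names <- c("time_high", "time_low", "ratio", "difference")
    events$sub_condition <- purrr::map2_chr(
      events$kind, events$onset_index,
      function(kind, i) {
        if (kind != "noncycling") return(NA_character_)
        hit <- which(sub_mat[i, ])
        if (length(hit) == 0) NA_character_ else sub_names[hit[1]]
      })
    events$onset_time <- (events$onset_index - 1) / fs
    events$clear_time <- (events$clear_index - 1) / fs
  }
  structure(list(events = events, active = active, thresholds = thresholds),
            class = "vent_alarms")
}

#' Collapse per-sample alarm activity into onset/clear events
#'
#' @param per_sample_active Per-sample activity: either a data frame of logical
#'   columns (one per alarm kind) or a list of character vectors of active
#'   kinds, one element per sample.
#' @return A tibble with one row per maximal run of consecutive activity per
#'   kind: `kind`, `onset_index` (first active sample, 1-based),
#'   `clear_index` (first sample after the run, `NA` if still active at the
#'   end of the record), ordered by onset.
#' @examples
#' alarm_timeline(data.frame(high_pressure = c(FALSE, TRUE, TRUE, FALSE)))
#' @export
alarm_timeline <- function(per_sample_active) {
  if (is.list(per_sample_active) && !is.data.frame(per_sample_active)) {
    kinds <- unique(unlist(per_sample_active))
    per_sample_active <- as.data.frame(
      lapply(stats::setNames(kinds, kinds), function(k) {
        vapply(per_sample_active, function(s) k %in% s, logical(1))
      }), optional = TRUE)
  }
  stopifnot(is.data.frame(per_sample_active))
  out <- purrr::map_dfr(names(per_sample_active), function(kind) {
    x <- per_sample_active[[kind]]
    if (!is.logical(x)) return(NULL)
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on) == 0) return(NULL)
    tibble::tibble(
      kind = kind,
      onset_index = starts[on],
      clear_index = ifelse(ends[on] == length(x), NA_integer_, ends[on] + 1L)
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(kind = character(0), onset_index = integer(0),
                          clear_index = integer(0)))
  }
  dplyr::arrange(out, .data$onset_index, .data$kind)
}

#' @export
print.vent_alarms <- function(x, ...) {
  cat(sprintf("<vent_alarms> %d event(s) over %d samples\n",
              nrow(x$events), nrow(x$active)))
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}

#' Alarm events from an alarm evaluation
#'
#' @param x A `vent_alarms` from [detect_alarms()].
#' @param ... Unused.
#' @return The event tibble (kind, onset, clear, noncycling sub-condition).
#' @export
tidy.vent_alarms <- function(x, ...) x$events

#' Plot alarm events as time segments over the record
#'
#' @param object A `vent_alarms` from [detect_alarms()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vent_alarms <- function(object, ...) {
  ev <- object$events
  end_time <- max(object$active$time)
  if (nrow(ev) > 0) {
    ev$clear_plot <- ifelse(is.na(ev$clear_time), end_time, ev$clear_time)
  }
  ggplot2::ggplot(ev, ggplot2::aes(y = .data$kind)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$onset_time,
                                       xend = .data$clear_plot,
                                       yend = .data$kind),
                          linewidth = 3, colour = "firebrick") +
    ggplot2::xlim(0, end_time) +
    ggplot2::labs(x = "time (s)", y = NULL)
}
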