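# CSV trace input/output, sensor-count calibration and YAML configuration.
# CSV is the single trace format: one column (`pressure`, needing an explicit
# sample rate) or two columns (`time`, `pressure`, from which the rate is
# inferred).

#' Read an airway-pressure trace from CSV
#'
#' Accepts a one-column (`pressure`) or two-column (`time`, `pressure`) CSV,
#' with or without a header. Two-column input infers the sample rate from the
#' median time step and rejects irregular sampling (time-step jitter above
#' 1%); one-column input requires an explicit `fs`.
#'
#' @param path Path to the CSV file.
#' @param fs Sample rate in samples/s; required for one-column input and, if
#'   supplied alongside a time column, overrides the inferred rate.
#' @return An object of class `pressure_trace`: a list with `fs`, `samples`
#'   (cm H2O) and `source` (the path).
#' @export
read_pressure_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header, strip.white = TRUE)
  if (ncol(df) == 1) {
    names(df) <- "pressure"
  } else if (ncol(df) == 2) {
    names(df) <- c("time", "pressure")
  } else {
    stop("Expected a 1-column (pressure) or 2-column (time,pressure) CSV; got ",
         ncol(df), " columns.", call. = FALSE)
  }
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  finite <- Reduce(`&`, lapply(df, is.finite))
  if (any(!finite)) {
    stop(sprintf("Non-numeric or non-finite value at data row %d of %s.",
                 which(!finite)[1], path), call. = FALSE)
  }
  if ("time" %in% names(df)) {
    steps <- diff(df$time)
    if (length(steps) < 1) stop("Need at least 2 samples to infer fs.", call. = FALSE)
    med <- stats::median(steps)
    if (med <= 0 || any(abs(steps - med) > 0.01 * med)) {
      stop("Irregular sampling: time-step jitter exceeds 1%; ",
           "resample the trace or supply a uniform time column.", call. = FALSE)
    }
    inferred <- 1 / med
    if (is.null(fs)) fs <- inferred
  } else if (is.null(fs)) {
    stop("One-column input needs an explicit sample rate `fs`.", call. = FALSE)
  }
  structure(list(fs = fs, samples = df$pressure, source = path),
            class = "pressure_trace")
}

#' Write an airway-pressure trace to CSV
#'
#' Writes a two-column `time,pressure` CSV with full double precision, so a
#' write/read round trip preserves values to better than 1e-9 and the sample
#' rate exactly.
#'
#' @param trace A `pressure_trace`, a `vent_sim`, or a data frame with `time`
#'   and `pressure` columns.
#' @param path Output path.
#' @param fs Sample rate, required only when `trace` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(trace, path, fs = NULL) {
  if (inherits(trace, "vent_sim")) {
    df <- trace$trace
  } else if (inherits(trace, "pressure_trace")) {
    df <- tibble::tibble(time = (seq_along(trace$samples) - 1) / trace$fs,
                         pressure = trace$samples)
  } else if (is.data.frame(trace)) {
    stopifnot(all(c("time", "pressure") %in% names(trace)))
    df <- trace[c("time", "pressure")]
  } else if (is.numeric(trace)) {
    if (is.null(fs)) stop("Supply `fs` to write a bare pressure vector.", call. = FALSE)
    df <- tibble::tibble(time = (seq_along(trace) - 1) / fs, pressure = trace)
  } else {
    stop("Unsupported trace type.", call. = FALSE)
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Linear sensor calibration
#'
#' Affine map from raw analog-to-digital converter counts to pressure, for
#' sensors with a linear pressure-to-voltage response (e.g. a 0-100 cm H2O
#' sensor on a 10-bit converter).
#'
#' @param offset Pressure at zero counts, cm H2O.
#' @param gain Pressure per count, cm H2O (nonzero).
#' @param count_range Integer vector `c(min, max)` of admissible counts.
#' @return An object of class `sensor_calibration`.
#' @examples
#' sensor_calibration(0, 100 / 1023, c(0, 1023))
#' @export
sensor_calibration <- function(offset = 0, gain = 100 / 1023,
                               count_range = c(0, 1023)) {
  stopifnot(is.numeric(offset), is.numeric(gain), length(count_range) == 2)
  if (gain == 0) stop("`gain` must be nonzero.", call. = FALSE)
  structure(list(offset = offset, gain = gain,
                 count_range = as.integer(count_range)),
            class = "sensor_calibration")
}

#' Convert raw sensor counts to pressure
#'
#' @param counts Integer sequence of converter counts.
#' @param cal A [sensor_calibration()].
#' @return Pressures in cm H2O: `offset + gain * counts`.
#' @examples
#' counts_to_pressure(1023, sensor_calibration()) # ~100 cm H2O full scale
#' @export
counts_to_pressure <- function(counts, cal = sensor_calibration()) {
  stopifnot(inherits(cal, "sensor_calibration"))
  bad <- which(counts < cal$count_range[1] | counts > cal$count_range[2] |
                 !is.finite(counts))
  if (length(bad) > 0) {
    stop(sprintf("Count %s at position %d outside range [%d, %d].",
                 format(counts[bad[1]]), bad[1],
                 cal$count_range[1], cal$count_range[2]), call. = FALSE)
  }
  cal$offset + cal$gain * counts
}

#' Write a monitoring configuration to YAML
#'
#' Serialises alarm thresholds and monitor settings as a flat key-value YAML
#' file mirroring the constructor arguments one-to-one. An empty file is a
#' valid configuration (all defaults).
#'
#' @param path Output path.
#' @param thresholds An [alarm_thresholds()].
#' @param config A [monitor_config()].
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(path, thresholds = alarm_thresholds(),
                              config = monitor_config()) {
  out <- list(
    fs = config$fs,
    alpha_attack = config$coefficients$alpha_attack,
    alpha_release = config$coefficients$alpha_release,
    alpha_smooth = config$alpha_smooth,
    p_max = thresholds$p_max, p_min = thresholds$p_min,
    rr_max = thresholds$rr_max, rr_min = thresholds$rr_min,
    t_max = thresholds$t_max, r_min = thresholds$r_min,
    d_min = thresholds$d_min, r_nom = thresholds$r_nom
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a monitoring configuration from YAML
#'
#' @param path Path to a YAML file written by [write_config_yaml()] (or hand
#'   authored with the same keys); missing keys take the package defaults.
#' @return A list with elements `thresholds` ([alarm_thresholds()]) and
#'   `config` ([monitor_config()]).
#' @export
read_config_yaml <- function(path) {
  y <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("File not found: ", path, call. = FALSE)
  if (is.null(y)) y <- list()
  fs <- y$fs %||% 100
  thresholds <- alarm_thresholds(
    p_max = y$p_max %||% 40, p_min = y$p_min %||% 5,
    rr_max = y$rr_max %||% 40, rr_min = y$rr_min %||% 8,
    t_max = y$t_max %||% 15, r_min = y$r_min %||% 1.5,
    d_min = y$d_min %||% 3, r_nom = y$r_nom %||% 2.4)
  coeffs <- tracker_coefficients(
    alpha_attack = y$alpha_attack %||% 0.9,
    alpha_release = y$alpha_release %||%
      release_coefficient(thresholds$r_min, thresholds$r_nom,
                          thresholds$t_max, fs))
  config <- monitor_config(fs = fs, coefficients = coeffs,
                           alpha_smooth = y$alpha_smooth %||% 0.5)
  list(thresholds = thresholds, config = config)
}
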