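# Alarm thresholds, the five alarm conditions, and event bookkeeping.

test_that("threshold validation names the violated tuning range", {
  expect_error(alarm_thresholds(p_max = 95), "p_max.*30-90")
  expect_error(alarm_thresholds(p_min = 0.5), "p_min.*1-20")
  expect_error(alarm_thresholds(rr_max = 70), "rr_max.*15-60")
  expect_error(alarm_thresholds(rr_min = 2), "rr_min.*5-15")
  expect_error(alarm_thresholds(t_max = 40), "t_max.*5-30")
  expect_error(alarm_thresholds(r_min = 1), "r_min")
  expect_error(alarm_thresholds(r_min = 2.5, r_nom = 2.4), "r_min")
  expect_error(alarm_thresholds(d_min = 0), "d_min")
})

test_that("instantaneous pressure and rate alarms compare against limits", {
  th <- alarm_thresholds(p_max = 90, p_min = 1)
  expect_identical(check_instant_alarms(95, NULL, th), "high_pressure")
  expect_identical(check_instant_alarms(0.5, NULL, th), "low_pressure")
  expect_identical(check_instant_alarms(45, NULL, th), character(0))

  th <- alarm_thresholds()
  m_fast <- list(rr = 55, valid = TRUE)
  m_slow <- list(rr = 4, valid = TRUE)
  m_warm <- list(rr = 55, valid = FALSE)
  expect_identical(check_instant_alarms(20, m_fast, th), "high_rr")
  expect_identical(check_instant_alarms(20, m_slow, th), "low_rr")
  expect_identical(check_instant_alarms(20, m_warm, th), character(0))
})

test_that("noncycling sub-conditions trigger independently (OR semantics)", {
  th <- alarm_thresholds()
  base <- init_monitor(monitor_config(fs = 100), 10)

  # Time since last high attack exceeding t_max * fs.
  st <- base
  st$high$samples_since_attack <- 1501L
  st$high$value <- 24; st$low$value <- 10
  out <- check_noncycling(st, th, 100)
  expect_true(out$active)
  expect_identical(out$sub_conditions, "time_high")

  st$low$samples_since_attack <- 1501L
  expect_setequal(check_noncycling(st, th, 100)$sub_conditions,
                  c("time_high", "time_low"))

  # Envelope ratio below r_min.
  st <- base
  st$high$value <- 14.9; st$low$value <- 10
  expect_identical(check_noncycling(st, th, 100)$sub_conditions, "ratio")

  # Envelope difference below d_min (3 cm H2O) with the ratio still healthy.
  st <- base
  st$high$value <- 3.5; st$low$value <- 2
  expect_identical(check_noncycling(st, th, 100)$sub_conditions, "difference")

  # Ratio guard: near-atmospheric low envelope skips the ratio test.
  st <- base
  st$high$value <- 0.4; st$low$value <- 0.3
  out <- check_noncycling(st, th, 100)
  expect_identical(out$sub_conditions, "difference")

  # Normal separation: nothing fires.
  st <- base
  st$high$value <- 24; st$low$value <- 10
  expect_false(check_noncycling(st, th, 100)$active)
})

test_that("alarm timeline collapses runs into onset/clear events", {
  expect_identical(nrow(alarm_timeline(data.frame(high_pressure = rep(FALSE, 50)))), 0L)

  x <- rep(FALSE, 300); x[100:199] <- TRUE
  ev <- alarm_timeline(data.frame(noncycling = x))
  expect_identical(ev$onset_index, 100L)
  expect_identical(ev$clear_index, 200L)

  x[250:300] <- TRUE # second run, active through the end
  ev <- alarm_timeline(data.frame(noncycling = x))
  expect_identical(ev$onset_index, c(100L, 250L))
  expect_identical(ev$clear_index, c(200L, NA_integer_))

  # List-of-sets input form.
  sets <- list(character(0), "high_pressure", c("high_pressure", "low_rr"),
               character(0))
  ev <- alarm_timeline(sets)
  expect_setequal(ev$kind, c("high_pressure", "low_rr"))
  expect_identical(ev$clear_index[ev$kind == "high_pressure"], 4L)
})

test_that("disconnect to atmosphere: low pressure at once, noncycling t_max later", {
  # Drop scheduled exactly at a breath peak (peaks at 3k + 1 s for the
  # 20 breaths/min default with inspiratory fraction 1/3).
  sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
    rr_set = 20, duration = 60,
    events = list(sim_event("disconnect_atmosphere", start = 28))))
  fit <- run_monitor(sim)
  ev <- tidy(detect_alarms(fit, alarm_thresholds()))

  drop_sample <- match(TRUE, sim$trace$pressure == 0)
  lp <- ev[ev$kind == "low_pressure", ]
  expect_identical(nrow(lp), 1L)
  expect_lte(abs(lp$onset_index - drop_sample), 1)

  nc <- ev[ev$kind == "noncycling", ]
  expect_identical(nrow(nc), 1L)
  expect_identical(nc$sub_condition, "time_high")
  expect_equal((nc$onset_index - drop_sample) / 100, 15, tolerance = 0.02)
})

test_that("partial disconnect held at PEEP alarms via time-since-peak", {
  sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
    rr_set = 20, duration = 60,
    events = list(sim_event("disconnect_partial", start = 30))))
  fit <- run_monitor(sim)
  ev <- tidy(detect_alarms(fit, alarm_thresholds()))
  nc <- ev[ev$kind == "noncycling", ]
  expect_identical(nrow(nc), 1L)
  # Measured from the last high-pressure attack event, onset is t_max later.
  last_attack <- max(which(fit$samples$t_high[seq_len(nc$onset_index)] == 0))
  expect_equal((nc$onset_index - last_attack) / 100, 15, tolerance = 0.01)
  # No pressure alarm: PEEP sits above p_min.
  expect_false("low_pressure" %in% ev$kind)
})

test_that("small noncycling oscillation trips the envelope-proximity guards", {
  sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
    rr_set = 20, duration = 80,
    events = list(sim_event("small_oscillation", start = 30, amplitude = 1))))
  al <- detect_alarms(run_monitor(sim), alarm_thresholds())
  ev <- tidy(al)
  nc <- ev[ev$kind == "noncycling", ]
  expect_gte(nrow(nc), 1L)
  # The high envelope stops seeing peaks first (timeout), and as it decays
  # into the oscillation band the ratio and difference guards take over and
  # keep the alarm raised even though attack events have resumed.
  expect_true(any(al$active$nc_ratio))
  expect_true(any(al$active$nc_difference))
  last <- nrow(al$active)
  expect_true(al$active$noncycling[last])
  expect_false(al$active$nc_time_high[last] || al$active$nc_time_low[last])
})

test_that("obstruction: momentary dip then steady high pressure", {
  sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
    rr_set = 20, duration = 70,
    events = list(sim_event("obstruction_high", start = 30))))
  ev <- tidy(detect_alarms(run_monitor(sim), alarm_thresholds()))
  expect_true("low_pressure" %in% ev$kind)  # the 2 cm H2O dip
  expect_true("noncycling" %in% ev$kind)    # constant pressure afterwards
  lp <- ev[ev$kind == "low_pressure", ]
  expect_false(is.na(lp$clear_index[1]))    # dip clears after ~0.5 s
})

test_that("a spontaneous patient breath raises only the low-pressure alarm", {
  # Dip placed in end-expiration (trough at t = 33 for the 20 breaths/min
  # cycle), pulling the airway from PEEP down to ~2 cm H2O.
  sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
    rr_set = 20, duration = 60,
    events = list(sim_event("spontaneous_breath", start = 32, depth = 8))))
  ev <- tidy(detect_alarms(run_monitor(sim), alarm_thresholds()))
  expect_true("low_pressure" %in% ev$kind)
  expect_false("noncycling" %in% ev$kind)
})

test_that("timeout and ratio thresholds act monotonically on onset times", {
  sim <- generate_waveform(waveform_spec(pip_set = 24, peep_set = 10,
    rr_set = 20, duration = 80,
    events = list(sim_event("disconnect_partial", start = 30))))
  fit <- run_monitor(sim)
  onset_nc <- function(th) {
    ev <- tidy(detect_alarms(fit, th))
    min(ev$onset_index[ev$kind == "noncycling"])
  }
  # Larger t_max never fires the timeout earlier.
  o1 <- onset_nc(alarm_thresholds(t_max = 10))
  o2 <- onset_nc(alarm_thresholds(t_max = 15))
  o3 <- onset_nc(alarm_thresholds(t_max = 25))
  expect_true(o1 <= o2 && o2 <= o3)
  # Larger r_min never fires the ratio sub-condition later.
  ratio_onset <- function(r_min) {
    a <- detect_alarms(fit, alarm_thresholds(r_min = r_min, t_max = 30))$active
    match(TRUE, a$nc_ratio)
  }
  r1 <- ratio_onset(1.3); r2 <- ratio_onset(1.5); r3 <- ratio_onset(1.8)
  expect_true(r1 >= r2 && r2 >= r3)
})

test_that("normal cycling raises no alarms across the dial range", {
  for (pip in c(20, 30, 40)) {
    sim <- generate_waveform(waveform_spec(pip_set = pip, rr_set = 20,
                                           duration = 40))
    ev <- tidy(detect_alarms(run_monitor(sim),
                             alarm_thresholds(p_max = max(40, pip + 10))))
    expect_identical(nrow(ev), 0L)
  }
})
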