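# Envelope tracker arithmetic, coefficient calibration and their closed forms.

test_that("attack and release branches evaluate the two-branch recurrence", {
  co <- tracker_coefficients(alpha_attack = 0.9, alpha_release = 0.999)
  s <- envelope_state("high", 10)

  up <- update_envelope(s, 20, co)
  expect_true(up$attacked)
  expect_equal(up$state$value, 0.9 * 10 + 0.1 * 20) # 11
  expect_equal(up$state$last_attack_value, 20)
  expect_identical(up$state$samples_since_attack, 0L)

  # Equality takes the attack branch and is a fixed point of the average.
  tie <- update_envelope(envelope_state("high", 15), 15, co)
  expect_true(tie$attacked)
  expect_equal(tie$state$value, 15)

  # Release branch with the calibrated coefficient (r_min=1.5, r_nom=2.4,
  # T_max=1500 samples): alpha_R = (0.5/1.4)^(1/1500) = 0.999313822583.
  aR <- release_coefficient(1.5, 2.4, 15, 100)
  expect_equal(aR, 0.999313822583, tolerance = 1e-12)
  rel <- update_envelope(envelope_state("high", 20), 10,
                         tracker_coefficients(0.9, aR))
  expect_false(rel$attacked)
  expect_equal(rel$state$value, 19.9931382258, tolerance = 1e-10)
  expect_identical(rel$state$samples_since_attack, 1L)

  # Low tracker mirrors the comparisons.
  lo <- update_envelope(envelope_state("low", 10), 5, co)
  expect_true(lo$attacked)
  expect_equal(lo$state$value, 0.9 * 10 + 0.1 * 5)
  expect_false(update_envelope(envelope_state("low", 10), 12, co)$attacked)

  expect_error(update_envelope(s, NaN, co), "[Ss]ignal")
  expect_error(update_envelope(s, Inf, co), "[Ss]ignal")
})

test_that("release coefficient calibration inverts the decay law", {
  # Round trip through r_min = 1 + alpha^Tmax (r_nom - 1), to 1e-12 relative.
  grid <- expand.grid(r_min = c(1.2, 1.5, 2.0), r_nom = c(2.1, 2.4, 3.0),
                      t_max = c(5, 15, 30), fs = c(10, 100))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- release_coefficient(g$r_min, g$r_nom, g$t_max, g$fs)
    expect_gt(a, 0); expect_lt(a, 1)
    back <- 1 + a^(g$t_max * g$fs) * (g$r_nom - 1)
    expect_equal(back, g$r_min, tolerance = 1e-12)
  }
  # Degenerate orderings are rejected, naming the ordering.
  expect_error(release_coefficient(1, 2.4), "r_min")
  expect_error(release_coefficient(0.8, 2.4), "r_min")
  expect_error(release_coefficient(2.4, 2.4), "r_nom")
  expect_error(release_coefficient(3, 2.4), "r_nom")
  # Limiting behaviour (at one-sample horizon the exponent is 1).
  expect_equal(release_coefficient(2.4 - 1e-12, 2.4, 1, 1), 1, tolerance = 1e-9)
  expect_equal(release_coefficient(1 + 1e-12, 2.4, 1, 1), 0, tolerance = 1e-9)
})

test_that("attack time constant is the 1/e memory of the averager", {
  expect_equal(attack_time_constant(0.9, 100), 0.0949122158, tolerance = 1e-8)
  expect_equal(attack_time_constant(exp(-1), 1), 1.0)
  expect_equal(attack_time_constant(0.5, 10), 0.1442695041, tolerance = 1e-8)
  expect_error(attack_time_constant(0, 100), "alpha")
  expect_error(attack_time_constant(1, 100), "alpha")
})

test_that("recursive release matches the closed form under constant input", {
  aR <- release_coefficient(1.5, 2.4, 15, 100)
  expect_equal(closed_form_release(0, 24, 10, aR), 24)
  # The calibrated decay reaches r_min * PEEP exactly at T_max.
  expect_equal(closed_form_release(1500, 24, 10, aR), 15, tolerance = 1e-9)
  expect_equal(closed_form_release(1e9, 24, 10, aR), 10, tolerance = 1e-6)

  # Bit-level agreement of the recursion with the geometric closed form over
  # long constant runs, for several coefficient/level combinations.
  for (case in list(list(start = 24, floor = 10, a = aR),
                    list(start = 5, floor = 30, a = 0.99),
                    list(start = -3, floor = 2, a = 0.97))) {
    co <- tracker_coefficients(alpha_attack = 0.5, alpha_release = case$a)
    dir <- if (case$start > case$floor) "high" else "low"
    s <- envelope_state(dir, case$start)
    got <- numeric(1500)
    for (t in 1:1500) {
      s <- update_envelope(s, case$floor, co)$state
      got[t] <- s$value
    }
    want <- closed_form_release(1:1500, case$start, case$floor, case$a)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("envelope values stay within observed bounds and high >= low", {
  co <- tracker_coefficients(fs = 100)
  withr::with_seed(42, {
    for (rep in 1:20) {
      p <- cumsum(rnorm(300)) + 15
      hi <- oracle_envelope(p, p[1], co$alpha_attack, co$alpha_release, "high")
      lo <- oracle_envelope(p, p[1], co$alpha_attack, co$alpha_release, "low")

      # Implementation agrees with the straight-line oracle, including the
      # attacked flag on ties and near-ties.
      sh <- envelope_state("high", p[1]); sl <- envelope_state("low", p[1])
      vh <- vl <- numeric(length(p)); ah <- al <- logical(length(p))
      for (t in seq_along(p)) {
        uh <- update_envelope(sh, p[t], co); sh <- uh$state
        ul <- update_envelope(sl, p[t], co); sl <- ul$state
        vh[t] <- sh$value; vl[t] <- sl$value
        ah[t] <- uh$attacked; al[t] <- ul$attacked
      }
      expect_equal(vh, hi$value); expect_identical(ah, hi$attacked)
      expect_equal(vl, lo$value); expect_identical(al, lo$attacked)

      # Convex-combination bound and tracker ordering.
      bounds <- range(c(p[1], p))
      expect_true(all(vh >= bounds[1] - 1e-12 & vh <= bounds[2] + 1e-12))
      expect_true(all(vl >= bounds[1] - 1e-12 & vl <= bounds[2] + 1e-12))
      expect_true(all(vh >= vl - 1e-12))
    }
  })
})

test_that("coefficient validation enforces attack-faster-than-release", {
  expect_error(tracker_coefficients(0.99, 0.9), "alpha_attack")
  expect_error(tracker_coefficients(-0.1, 0.9), "alpha_attack")
  expect_error(tracker_coefficients(0.5, 1.2), "alpha_release")
  # Default attack coefficient preserves the ~100 ms memory across rates.
  expect_equal(tracker_coefficients(fs = 100)$alpha_attack, 0.9)
  expect_equal(attack_time_constant(tracker_coefficients(fs = 10)$alpha_attack, 10),
               attack_time_constant(0.9, 100), tolerance = 1e-12)
})
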