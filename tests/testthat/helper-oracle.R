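# Straight-line re-implementations used as independent oracles. These follow
# the defining recurrences directly, without any of the package's state
# objects, and are deliberately kept dumb.

# One envelope tracker over a whole series: v[t] from the two-branch
# recurrence, plus which samples took the attack branch.
oracle_envelope <- function(p, init, alpha_attack, alpha_release,
                            direction = c("high", "low")) {
  direction <- match.arg(direction)
  v <- numeric(length(p))
  attacked <- logical(length(p))
  prev <- init
  for (t in seq_along(p)) {
    att <- if (direction == "high") p[t] >= prev else p[t] <= prev
    a <- if (att) alpha_attack else alpha_release
    prev <- a * prev + (1 - a) * p[t]
    v[t] <- prev
    attacked[t] <- att
  }
  list(value = v, attacked = attacked)
}

# Breath-cycle transitions found by scanning for the first sample at which
# each envelope's attack branch fires (strictly) after the opposite tracker's
# phase, starting in exhalation. Returns transition indices/types and the
# completed-cycle count.
oracle_transitions <- function(p, alpha_attack, alpha_release) {
  vh <- vl <- p[1]
  inhaling <- FALSE
  idx <- integer(0)
  type <- character(0)
  n_cycles <- 0L
  for (t in seq_along(p)[-1]) {
    if (p[t] > vh && !inhaling) {
      inhaling <- TRUE
      idx <- c(idx, t); type <- c(type, "to_inhale")
    }
    vh <- (if (p[t] >= vh) alpha_attack else alpha_release) * vh +
      (1 - (if (p[t] >= vh) alpha_attack else alpha_release)) * p[t]
    if (p[t] < vl && inhaling) {
      inhaling <- FALSE
      idx <- c(idx, t); type <- c(type, "to_exhale")
      n_cycles <- n_cycles + 1L
    }
    vl <- (if (p[t] <= vl) alpha_attack else alpha_release) * vl +
      (1 - (if (p[t] <= vl) alpha_attack else alpha_release)) * p[t]
  }
  list(index = idx, type = type, n_cycles = n_cycles)
}

# A deterministic 40-sample toy breath: 10 -> 24 over 20 samples, back down
# over 20 samples.
toy_breath_trace <- function() {
  c(seq(10, 24, length.out = 20), seq(24, 10, length.out = 20)[-1], 10)
}
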