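---
title: "Envelope-based monitoring of pressure-cycled ventilators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope-based monitoring of pressure-cycled ventilators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmonitor)
```

## The problem

Pressure-cycled pneumatic ventilators switch between inhalation and
exhalation when the airway pressure crosses two thresholds: the peak
inspiratory pressure (PIP) and the positive end-expiratory pressure (PEEP).
They need no electronics to run, which makes them attractive as emergency
devices, but for the same reason they have no built-in monitoring: no
display of PIP, PEEP or respiratory rate (RR), and no alarm when the
breathing circuit disconnects, obstructs, or simply stops cycling. All of
that information is, however, present in the airway-pressure signal itself,
which cycles between PEEP and PIP once per breath.

`ventmonitor` implements a streaming monitor for that signal. It is designed
around the constraints of the embedded devices it models: a fixed, small
number of arithmetic operations per sample and a state of two envelope
values, two breath-cycle extrema, three counters and three smoothed metrics
— no buffer of past samples. (A rolling max/min over a two-second window at
100 samples/s would store 200 samples; each envelope tracker stores one
value.)

## Envelope trackers

The core primitive is a pair of nonlinear one-pole recursive averagers. For
pressure samples $p[t]$, the high-pressure envelope is

$$
v_{\text{high}}[t] =
\begin{cases}
\alpha_A\, v_{\text{high}}[t-1] + (1-\alpha_A)\, p[t], & p[t] \ge v_{\text{high}}[t-1]\\
\alpha_R\, v_{\text{high}}[t-1] + (1-\alpha_R)\, p[t], & p[t] < v_{\text{high}}[t-1]
\end{cases}
$$

and the low-pressure envelope mirrors the comparisons. The *attack*
coefficient $\alpha_A$ is small so the envelope snaps onto the signal in its
fast direction; the *release* coefficient $\alpha_R$ is close to 1 so the
envelope lets go slowly, riding over within-breath fluctuations. A sample
that takes the fast branch is an *attack event*; the tracker records the raw
pressure at its most recent attack event ($V_{\text{high}}$ or
$V_{\text{low}}$) and counts samples since it ($T_{\text{high}}$,
$T_{\text{low}}$). Under a constant input the release recursion has the
closed form implemented by `closed_form_release()`, which the tests use as
an analytic oracle for the recursive path.

### Coefficient defaults, with units

* `alpha_attack`: the design target is an attack-mode 1/e memory of about
  100 ms (`attack_time_constant(0.9, 100)` = 0.095 s). The default is
  therefore `0.9^(100/fs)` — exactly 0.9 at 100 samples/s and the same
  *time* constant at any other rate. Holding the *coefficient* rather than
  the time constant fixed would, at 10 samples/s, stretch the attack memory
  to about one second; the envelope then trails the waveform so badly that
  post-peak samples on the falling limb still take the attack branch, and
  the recorded breath-cycle maximum lands more than 1 cm H2O below the true
  peak. That effect is directly visible in the sample-rate experiment below.
* `alpha_release`: set analytically by `release_coefficient()`, see the
  alarm calibration section. At the defaults
  ($r_{\min}=1.5$, $r_{\text{nom}}=2.4$, $T_{\max}=15$ s, 100 samples/s)
  it is 0.9993138.
* Ties ($p[t]$ equal to the envelope) take the attack branch, which keeps
  the envelope arithmetic exact on plateaus.

## Breath detection and metrics

The monitor holds a binary inhaling/exhaling state. The first high-pressure
attack event of a cycle switches it to inhaling and updates the PEEP
estimate with the last low-pressure attack value; the first low-pressure
attack event switches it to exhaling, updates PIP with the last
high-pressure attack value, smooths the peak-to-peak breath period and
recomputes RR $= 60 f_s / T_b$. All three metrics update exactly once per
breath, regardless of the sample rate. Per-breath quantities are smoothed
recursively with $\alpha_S = 0.5$ (each past breath's contribution halves
per update).

Three startup/degeneracy choices are deliberate and worth stating:

* **Transitions require a strict comparison.** The envelope update keeps the
  tie-attacks rule, but a tie never toggles the breath state. On any real
  (non-plateau) signal the first attack of a run is strict, so this changes
  nothing; on an exactly constant signal it prevents the state machine from
  fabricating a breath per sample out of simultaneous high/low tie-attacks.
  A constant input therefore produces no transitions, ever.
* **First-cycle seeding.** The first completed measurement of PIP, PEEP and
  period initialises the corresponding smoothed value directly; smoothing a
  measurement against an undefined prior (or an RR of zero, whose inverse
  the period update would need) has no sensible value. The first
  peak-to-peak interval after startup is discarded entirely, because the
  monitor may have started mid-breath; metrics are flagged `valid` only
  once PIP, PEEP and a period have all been measured.
* **Initialisation.** Both envelopes start at the first pressure sample, so
  no spurious attack fires at startup, and the breath state starts as
  exhaling so the first rising edge registers as an inhalation.

Reported values are additionally rounded to a display resolution of
1 cm H2O and 1 breath/min (`pip_disp` etc. in the per-breath table); alarm
logic always uses the unrounded values.

## Alarm engine

Five alarm kinds are evaluated every sample:

| alarm | condition | default | tunable range |
|---|---|---|---|
| high pressure | $p[t] > p_{\max}$ | 40 | 30–90 cm H2O |
| low pressure | $p[t] < p_{\min}$ | 5 | 1–20 cm H2O |
| high RR | $RR > RR_{\max}$ | 40 | 15–60 breaths/min |
| low RR | $RR < RR_{\min}$ | 8 | 5–15 breaths/min |
| noncycling | any of four sub-conditions | — | $T_{\max}$: 5–30 s |

Defaults other than $T_{\max}=15$ s (a stated device default) are mid-range
choices. The noncycling sub-conditions are OR-ed: time since the last
high-pressure attack or since the last low-pressure attack exceeding
$T_{\max}$, envelope ratio $v_{\text{high}}/v_{\text{low}} < r_{\min}$
(default 1.5), or envelope difference $< d_{\min}$ (3 cm H2O). The time
conditions catch a flat-lined signal; the proximity conditions catch a
signal that still wiggles enough to generate attack events but no longer
cycles.

### Release calibration

The release coefficient ties the ratio condition to the timeout. If the
pressure fell instantly from PIP to PEEP and stayed there, the high envelope
would decay as
$v_{\text{high}}[t] = \text{PEEP} + \alpha_R^{\,t}(\text{PIP}-\text{PEEP})$,
and the ratio condition fires when $v_{\text{high}} = r_{\min}\cdot
\text{PEEP}$. Requiring that moment to be $T_{\max}$, for a ventilator whose
mechanical PIP-to-PEEP ratio is $r_{\text{nom}}$, gives

$$
\alpha_R = \left(\frac{r_{\min}-1}{r_{\text{nom}}-1}\right)^{1/T_{\max}},
$$

with $T_{\max}$ in samples ($T_{\max} f_s$ when given in seconds, which is
how the interface accepts it, since the tunable range is quoted in
seconds). The test suite verifies that on such a step drop the ratio and
timeout sub-conditions fire within one sample of each other.

### Warm-up and guards

At initialisation both envelopes are equal, so the ratio and difference
sub-conditions would alarm instantly. They are suppressed until metrics
first become valid or $T_{\max}$ has elapsed, whichever comes first. The
*first completed breath cycle* is deliberately read as *metrics valid* (two
high-pressure peaks observed) rather than the first transition: under noise
a single spurious transition can occur within the first few samples while
the envelopes still hug each other, and ending warm-up there would fire a
false difference alarm. The time sub-conditions run from startup — they
cannot fire before $T_{\max}$ anyway. Separately, the ratio sub-condition is
skipped whenever $v_{\text{low}} < 0.5$ cm H2O: a pressure ratio near
atmospheric is meaningless, the low-pressure alarm owns that regime, and
assisted breathing can legitimately pull the airway to ~0. Alarms auto-clear
when their condition clears; latching and buzzer/mute semantics are
hardware-UI concerns outside this package's scope.

## The waveform simulator

No public recordings of these devices exist, so every behaviour is
exercised against `generate_waveform()`, which emulates the
pressure-switching mechanism directly rather than modelling lung mechanics
(no published compliance/resistance values exist for the recordings the
algorithm was originally validated on). Within each cycle of period
$60/\text{rr}$ s, pressure approaches a target slightly above PIP with time
constant `tau_insp` during inspiration and a floor slightly below PEEP with
`tau_exp` during expiration; the target and floor are *solved* so that the
noiseless trace reaches PIP exactly at end-inspiration and PEEP exactly at
end-expiration. Phase switching at the set points is thereby exact by
construction, and the noiseless trace touches each set point once per cycle
and never overshoots it.

Defaults, chosen once as a realistic mandatory-ventilation condition: PIP
24 cm H2O, PEEP = PIP/2.4 (the fixed mechanical ratio of the emulated
device class), 20 breaths/min, inspiratory fraction 1/3, `tau_insp` 0.3 s
and `tau_exp` 0.8 s (roughly 2.5–3 time constants per phase at the default
rate, giving the rounded approach to both set points characteristic of
these devices), sensor noise as seeded additive white Gaussian with
sd 0 by default (0.3 cm H2O is used as the noisy test condition). The time
constants are fixed in seconds — turning the rate dial shortens the phases,
so fast breathing genuinely sharpens the peak and truncates the trough, as
it does pneumatically.

Scheduled events overlay failure scenarios: full disconnect to atmosphere,
partial disconnect holding an arbitrary pressure, obstruction (momentary dip
then steady high pressure), PIP dial changes (ramped over one cycle, as a
clinician would turn a dial, or stepped for the calibration tests),
spontaneous patient breaths dipping below PEEP, and a small noncycling
oscillation that exercises the envelope-proximity guards specifically.
Ground truth (per-cycle PIP/PEEP/period, event windows) is emitted alongside
the trace.

What the simulator does *not* reproduce: correlated/impulsive sensor noise,
cardiogenic oscillations, patient-ventilator asynchrony beyond a single
scripted dip, slow drifts in the dial settings, and real lung dynamics. A
pass on synthetic data therefore demonstrates the algorithm's logic and
calibration, not clinical performance.

## Numerical behaviour and known limitations

* The recursion under constant input agrees with the geometric closed form
  to better than 1e-9 relative over 1500-step runs, and the calibration
  formula round-trips through the decay law to 1e-12; both are asserted in
  the tests.
* PIP and PEEP estimates are raw pressure samples captured at attack events,
  so they inherit two small biases that no amount of smoothing removes
  (smoothing reduces variance, not bias). With white measurement noise, the
  recorded extremum of a flat trough is biased low by a couple of noise
  standard deviations (and symmetrically for sharp peaks); and at fast
  breathing rates the ~100 ms attack memory records the last attack one or
  two samples onto the opposite limb, biasing PEEP slightly high and PIP
  slightly low. In the test grid (PIP 20–40 cm H2O, 10–35 breaths/min,
  noise sd up to 0.3 cm H2O) every resulting error stays within the 1 cm
  H2O / 1 breath/min display resolution, which is the accuracy the display
  rounds to anyway; a tighter 2%-of-true-value band holds everywhere for
  PIP and RR but not for PEEP at the grid corners (slow noisy troughs, fast
  sharp troughs).
* The sample-rate experiment (`sample_rate_experiment()`, also the
  `experiment sample-rate` CLI subcommand) uses five 120 s realisations of
  a 35 breaths/min, noise-sd 0.3 waveform at 100 samples/s, decimated by
  keeping every $k$-th sample; per-breath estimates are compared after a
  five-breath burn-in. At 10 samples/s the RMS differences are ~0.23 cm H2O
  (PIP) and ~0.40 breaths/min (RR); at 5 samples/s breaths are missed
  outright and RR error grows an order of magnitude, so 10 samples/s is the
  practical floor.
* Sub-second breath periods (rates above ~60/min) and negative gauge
  pressures below one display step are outside the design envelope.

## Scope

The package covers the signal path from a pressure trace (CSV, or raw
converter counts through a linear `sensor_calibration()`) to metrics and
alarm events. Tidal volume and oxygen concentration cannot be inferred from
a single pressure signal and are out of scope, as are firmware concerns
(fixed-point arithmetic, display/buzzer control).
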