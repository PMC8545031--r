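Package: ventmonitor
Title: Streaming Envelope-Based Monitoring and Alarms for Pressure-Cycled Ventilators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring pressure-cycled (pneumatic) ventilators from a
    single airway-pressure signal. A pair of nonlinear recursive attack/release
    envelope trackers follows the top and bottom of the pressure waveform using
    one stored value per tracker; a single-pass breath-cycle state machine
    estimates peak inspiratory pressure (PIP), positive end-expiratory pressure
    (PEEP) and respiratory rate once per breath; and a five-condition alarm
    engine (high/low pressure, high/low respiratory rate, noncycling) flags
    ventilator malfunction, including an analytically calibrated release
    coefficient that makes the envelope-ratio and time-since-last-peak
    noncycling triggers coincide on a step drop. A ground-truth-annotated
    waveform simulator emulates normal cycling, assisted breathing and failure
    scenarios (disconnect, obstruction, dial changes, small noncycling
    oscillations) so every behaviour is testable without hardware. Includes CSV
    input/output and a command-line interface for simulate, monitor, sample-rate
    experiment and calibration workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
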