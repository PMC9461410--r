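Package: vaxwatch
Title: Detecting Physiological Reactions to Vaccination from Smartwatch Data
Version: 0.1.0
Authors@R: person("PerMed", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for active surveillance of vaccine reactogenicity that
    combine consumer-smartwatch physiology (heart rate, a 1-100 stress index)
    with daily symptom questionnaires. Implements symptom severity tiering
    with baseline subtraction, hourly aggregation of raw wearable streams
    with gap interpolation and moving-average smoothing, day-of-week and
    hour-of-day baseline-matched differencing, stratified cohort statistics
    with Welch tests and beta-distribution proportion intervals, and a
    mixed-effects panel regression with a lagged dependent variable and
    participant random intercepts. Ships a synthetic cohort generator that
    emulates circadian baselines, severity-dependent post-vaccination
    response curves, device-charging gaps, and probabilistic symptom
    reporting, so the full pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
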