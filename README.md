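# vaxwatch

Active surveillance of vaccine reactogenicity from consumer-smartwatch
data. The package compares post-vaccination physiology — heart rate
(beats/min, 15 s cadence) and a heart-rate-variability-derived stress
index (1–100, 3 min cadence) — against each participant's own baseline
week, and against what the participant reported in a daily symptom
questionnaire. It is aimed at biostatisticians and digital-epidemiology
groups analysing wearable cohorts around a known exposure time (here:
BNT162b2 doses 2 and 3), and at anyone who needs a tested, synthetic-data-
backed reference implementation of this class of pipeline.

## What it computes

1. **Severity tiering.** Daily questionnaires are deduplicated to the last
   entry per local day; symptoms are classified mild/severe from a
   controlled vocabulary ("feeling hot" becomes fever only above 38.9 °C);
   baseline-week symptoms are subtracted; the participant's tier is the
   maximum severity of the remaining symptoms within 72 h of the dose.
   Reporting proportions carry Beta(k, n−k) 95% intervals.
2. **Baseline-matched differencing.** Raw streams are averaged per
   wall-clock hour; missing runs shorter than 5 h are linearly
   interpolated, longer runs stay excluded; a centred 5 h moving average
   smooths the series; post-vaccination hour *h* ∈ [0, 336) is differenced
   against baseline hour (*h* mod 168) − 168 — identical day-of-week and
   hour-of-day:

   Δᵢ(h) = yᵢ(h) − yᵢ((h mod 168) − 168).

3. **Cohort statistics.** Hourly mean-difference curves with
   across-participant t 95% CIs, 72 h window means stratified by severity
   tier, two-sided Welch t-tests between tiers, and peak /
   return-to-baseline summaries.
4. **Panel regression.** One row per participant-hour over [−168, 168)
   (interpolated, unsmoothed):

   yᵢₜ = β₀ + β₁·post72ᵢₜ + β₂·yᵢ,ₜ₋₁ + β₃·ageᵢ + β₄·no_condᵢ + β₅·maleᵢ + uᵢ + εᵢₜ,

   uᵢ ~ N(0, σ²ᵤ), fitted by ML (`lme4`), with the one-sided test of β₁ at
   the Bonferroni threshold 0.05/6 → 0.008, the variance share
   σ²ᵤ/(σ²ᵤ+σ²ₑ), between/within/overall R², and a 24–72 h sensitivity
   refit.
5. **Synthetic cohorts.** A seeded generator (circadian baselines,
   participant random effects, severity-anchored response curves peaking
   at 24 h, charging gaps, probabilistic symptom reporting) makes the whole
   pipeline testable with known ground truth — no real data required.

## Worked example

```r
library(vaxwatch)
cfg <- simulation_config(n_participants = 12, seed = 42)
res <- run_pipeline(config = cfg, out_dir = "vaxwatch-out")
writeLines(res$report)
```

prints (excerpt):

```
channel heart_rate:
  all     72h mean diff 2.95 [2.18, 3.72] (n=12); peak 6.01 at 23h, return at 111h
  mild    72h mean diff 2.58 [2.16, 2.99] (n=5); peak 5.80 at 22h, return at 70h
  none    72h mean diff 2.02 [1.13, 2.92] (n=4); peak 5.07 at 38h, return at 83h
  severe  72h mean diff 4.81 [4.21, 5.41] (n=3); peak 10.07 at 24h, return at 69h

panel heart_rate_all [0-72h] (n = 12 participants, 3991 observations)
  Term                                          Coef,  StdErr, p
  Intercept                                  32.8038,  2.5671, <0.001
  Between 0 and 72 h after vaccination        1.4197,  0.1467, <0.001
  HR or Stress in Previous Hour               0.4871,  0.0138, <0.001
  ...
  % of Variance due to Random Effects: 20.72%
  post-72h indicator one-sided p 3.36e-22 -> significant at Bonferroni 0.008
  sensitivity [24-72h] coefficient 1.3745
```

Reading it: the simulated cohort's 72 h mean heart-rate elevation is
ordered none < mild < severe (the generator injects 2.8/5/9 bpm peaks at
24 h, and smoothing/averaging dilutes a peak into a smaller window mean);
the panel regression detects a positive post-vaccination shift per hour
after removing the lag, demographics and participant random intercepts.
Per-stage CSVs (tiers, proportions, inclusion with exclusion reasons,
hourly series, matched differences, curves, tests) land in `out_dir`.

The same stages are scriptable:

```sh
Rscript -e 'vaxwatch::vaxwatch_cli()' simulate --n 50 --seed 1 --out sim
Rscript -e 'vaxwatch::vaxwatch_cli()' run --roster sim/roster.csv \
    --wearable sim/wearable.csv --questionnaires sim/questionnaire.csv \
    --out results
```

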