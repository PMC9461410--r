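---
title: "Methods: detecting vaccine reactogenicity from smartwatch data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting vaccine reactogenicity from smartwatch data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxwatch)
```

## The problem

Vaccine safety surveillance leans on self-reported symptom diaries, which
are subjective, discontinuous, and insensitive. Consumer smartwatches
record heart rate (15-second cadence) and a heart-rate-variability-derived
stress index (1–100, 3-minute cadence) continuously, so a physiological
response to vaccination — an elevation over the participant's own baseline
peaking roughly a day after the dose — can be measured objectively and
compared against what the participant reported. `vaxwatch` implements that
comparison as a reusable pipeline: severity tiering of daily symptom
questionnaires, baseline-matched differencing of the wearable channels,
stratified cohort statistics, and a lagged mixed-effects panel regression.

## Severity tiering

A symptom is *severe* if it is one of chest pain, dyspnea, fever,
confusion, chills; the remaining checklist symptoms are *mild*. "Feeling
hot" escalates to fever only when a recorded temperature strictly exceeds
38.9 °C; an unrecorded temperature is treated as below threshold. A
temperature of exactly 38.9 °C is mild — "above 38.9" is read strictly.

Per participant and dose, only the last questionnaire entry per local
calendar day is kept (entries cannot be edited, only resubmitted, so the
last one reflects the day). Symptoms present in the last baseline-week
entry are assumed pre-existing and removed from all post-vaccination
entries before tiering; we subtract a baseline symptom entirely, since the
questionnaire carries no severity grading with which to detect worsening.
The participant's tier is the maximum severity of the remaining symptoms
over the 72 h after the vaccination *timestamp* (not the start of the
vaccination day). Free-text symptoms are accepted on input but ignored for
tiering with a warning, as they have no severity mapping.

Reporting proportions use a Beta(k, n − k) interval at the 2.5% and 97.5%
quantiles. At k = 0 or k = n one Beta parameter vanishes and the
distribution degenerates to a point mass, so the interval collapses to
[0, 0] or [1, 1] — the one-sided limit of the stated interval. Stratified
percentages are rounded half-up to one decimal for reporting.

## Wearable preprocessing

The chain is fixed: hourly averaging → gap interpolation → 5 h moving
average → baseline matching. Hour cells align to wall-clock hour
boundaries, not vaccination-anchored offsets, because matching is
calendar-based (Tuesday 22:00 post vs Tuesday 22:00 baseline); the integer
hour index is taken relative to the hour containing the vaccination
timestamp afterwards.

* **Interpolation.** Missing runs of 1–4 h bounded by observed cells are
  filled linearly. Runs of exactly 5 h are *not* filled: the stated rules
  ("fewer than 5 h interpolated", "more than 5 h excluded") leave length 5
  ambiguous and we resolve it conservatively as excluded. Runs touching a
  series edge are never filled.
* **Smoothing.** The moving average is centred (±2 h), which preserves peak
  timing; the window mean is taken over the non-missing cells available,
  so edge hours use a partial window rather than being dropped. Missing
  cells stay missing — smoothing never reintroduces values into excluded
  hours.
* **Matching.** The baseline is exactly the 168 h before vaccination, so
  post hour h (0 ≤ h < 336) matches baseline hour (h mod 168) − 168, which
  has the identical day-of-week and hour-of-day; the second post week
  reuses the same baseline week. A difference exists only where both cells
  are non-missing.

All timestamps are local clock time handled in a fixed zone; a DST
transition inside an analysis window would shift the circadian alignment
by an hour and is a documented limitation, not modelled.

## Inclusion

A participant-dose is analysed only with (1) a baseline-week
questionnaire, (2) a questionnaire within 72 h post-dose, and (3) at least
one matched non-missing wearable cell pair. Wearable data confined to a
single calendar day in either period excludes the participant *unless*
that day is calendar-matched in the other period, in which case the
matched hours are used. Decisions are per dose and deterministic.

## Cohort statistics

Hourly cohort curves average the matched differences across participants,
with t-distribution 95% intervals across participants (chosen over normal
quantiles for small strata; the across-participant interpretation follows
from "mean difference over participants"). The 72 h window summary averages
each participant's available hourly differences, then summarises across
participants. Between-tier comparisons use the two-sided Welch t-test with
Welch–Satterthwaite degrees of freedom. "Return to baseline" is
operationalised as the first post-peak hour from which the hourly CI
contains zero for 24 consecutive hours — the narrative phrase has no
printed rule, and sustaining the condition for a day avoids counting a
single noisy hour as a return.

## Panel regression

One row per participant-hour over [−168, 168) built from interpolated but
*unsmoothed* data: y on a post-vaccination indicator (0–72 h), the 1-hour
lagged y, age, no-underlying-condition and male indicators, with
participant random intercepts, fitted by maximum likelihood (`lme4`; the
estimation method is not pinned down by the source design — ML was chosen
and is what the test oracle, an independent profiled-likelihood GLS,
implements). The lag is taken within participant and within contiguous
runs; each run's first hour is dropped, so a fully observed participant
contributes 335 rows.

A lagged dependent variable alongside participant effects induces
Nickell-type bias of order 1/T; at T = 336 it is negligible, and the
package follows the published design rather than correcting it (parameter
recovery at that T is part of the acceptance suite). Coefficient p-values
are two-sided t-tests (df = n − 6); the indicator additionally reports a
one-sided p (alternative: positive), judged against the Bonferroni
threshold 0.05/6 → 0.008. The F statistic is the Wald test of all slopes
jointly zero. R² between/within/overall are squared correlations of
fixed-part fitted values with participant means, demeaned values, and raw
values respectively. The sensitivity refit replaces the indicator window
with 24–72 h; with a response that is near baseline in the first 12 h, its
coefficient exceeds the main fit's.

## The synthetic generator

The generator is the stated world the tests run in. Per channel, a sample
is

> participant baseline + circadian term + severity response + noise,

with defaults: heart-rate level 65 bpm (circadian amplitude 4 bpm), stress
level 30 points (amplitude 8); a single 24 h sinusoid with trough at 04:00
(the simplest shape that makes calendar matching non-trivial);
between-participant SD 6 bpm / 8 points; an hour-level within-participant
disturbance (3 bpm / 7 points) shared by all samples in an hour, standing
in for activity and posture, plus sample-level noise (5 bpm / 15 points).
Stress is clipped to [1, 100] and heart rate floored at 30 bpm. Severity
mix defaults to 55/35/10%, the third-dose tier proportions.

The response curve is a log-normal-shaped pulse: zero at and before the
dose, peak at 24 h, half-height times set by rise (12 h) and decay (24 h)
parameters, smooth and vanishing at infinity. Peak elevations default to
2.8/5/9 bpm and 6/10/21 stress points for none/mild/severe, anchored to
the third-dose magnitudes reported for those strata; the severe stress
curve adds a delayed negative undershoot so the cohort dips below baseline
before recovering around day 11. Device-charging gaps arrive as a Poisson
process (0.3/day) with exponential lengths (mean 2 h), which makes >5 h
gaps — and hence the exclusion path — a regular occurrence at cohort
scale. Questionnaires are submitted each evening (the within-day timing is
unstated in the source design; evening submission is the natural reading
of an end-of-day diary and only matters for the last-entry rule) with 95%
compliance, occasional same-day duplicates to exercise deduplication, and
per-severity reporting probabilities that deliberately allow severe
physiology with no reported symptoms. Every draw comes from a
per-participant substream of the master seed, so output is bit-reproducible
and growing the cohort never reshuffles existing participants.

For cohort-scale simulation studies, `simulate_hourly()` emits the hourly
means directly (circadian term integrated analytically, response curve
averaged at four in-hour quadrature points, sample noise shrunk by the
square root of the per-hour sample count). It matches the raw-cadence path
to within ~0.05 bpm and runs orders of magnitude faster; replicated
acceptance studies use it, single-stream unit tests use the raw path.

A green test establishes that the pipeline recovers what this world
injects — amplitude ordering, the 0.7 panel coefficient, an 8%
random-intercept share, nominal type-I error — not that real Garmin data
satisfies the model: the generator has no activity confounders, no
proprietary stress algorithm (stress is simulated directly on its scale,
not derived from heart-rate variability), integer-free values, and no
attrition beyond charging gaps.

## Numerical and degenerate-input choices

Zero-variance groups in the Welch test: equal means return p = 1, unequal
means are an error. Hours with a single contributor carry no CI. Empty
strata yield empty curves with a message. Mixed channels or a malformed
baseline window are errors, not warnings. The published cross-tabulation
arithmetic is reproduced through `crosstab_from_counts()`, which expands
printed counts into pseudo-participants and runs the same `tier_crosstab()`
code path as real cohorts; two percentages printed in the source table
(15.6%, 34.2%) are inconsistent with its own printed counts (52/335 →
15.5%, 404/1179 → 34.3%) and the tests assert the exact arithmetic.

## Known limitations

No artifact rejection or motion filtering; no DST handling; free-text
symptoms are dropped rather than mapped; the generator's reporting model is
Bernoulli-per-day rather than episode-structured; and the paper-scale
headline estimates (e.g. a 2.77 bpm asymptomatic peak) are anchors for the
generator's defaults, not quantities recomputed from unavailable raw data.
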