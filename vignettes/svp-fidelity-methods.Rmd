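---
title: "Staged fidelity assessment of voiding-programme clinical logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged fidelity assessment of voiding-programme clinical logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpfidelity)
```

## The assessment model

A systematic voiding programme (SVP) prescribes, for each patient-day, a
fixed voiding interval and a schedule of proposed toileting times running
from 07:30 to 21:30, with the aim that the patient voids within 30 minutes
of each proposed time. Fidelity to delivery is assessed from the daily
clinical log — the form on which staff document the interval, the schedule,
the actual voids and the best-practice answers.

Because a comparison of actual against proposed times is only meaningful
when its prerequisites hold, the assessment is *staged*: each prerequisite
is a key quality indicator (KQI), and a log that fails Stage 1 or Stage 2 is
not examined further.

* **Stage 1 — interval validity.** The interval must be a single number
  ("2-hourly"), not blank and not a range ("2 – 3 hourly"): a range does not
  define a schedule. `parse_interval()` is total and deterministic; every
  string maps to exactly one of `single` / `range` / `missing` /
  `unparseable`, with half-hour values ("2.5-hourly" = 150 min) supported.
* **Stage 2 — schedule correctness.** At least two proposed times; no
  missing entry between the first and last documented proposed time; every
  consecutive gap *identical* to the interval. A log with one proposed time
  fails (`no_proposed_times`): a single time cannot demonstrate the
  interval, and we treat this conservatively as an unverifiable schedule.
  Schedules that cover less than the full 07:30–21:30 window do **not**
  fail — the indicator demands completeness between endpoints and correct
  gaps, nothing more — but the uncovered span is returned as
  `span_shortfall_minutes` so day-coverage can be monitored separately.
* **Stage 3 — adherence within the leeway.** For each proposed time, was an
  actual void documented within the window? Occasions with a clinically
  justifiable explanation are exempted from numerator and denominator.
* **Stage 4 — best-practice documentation.** Counts of literal `"yes"`
  answers per proposed voiding time; a blank and a "no" both count as
  not-yes, and the two are kept distinct end-to-end because staff often
  leave an answer blank precisely when the component was not done.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `window_minutes` | 30 | min | The SVP's agreed leeway. The boundary is **inclusive** (&#124;Δ&#124; ≤ 30): "within 30 min" is read in its natural inclusive sense, fixed here so tests are exact. |
| `tolerance_minutes` | 0 | min | Stage-2 gaps must equal the interval *identically*; the tolerance exists for transcription slop but defaults to the strict rule. |
| `exemption_codes` | 4 placeholder codes | — | The clinical criteria for a justifiable exemption live in trial documents, not in this package; which codes exempt is therefore configuration. The simulator emits codes from the same default list. |
| `day_start`, `day_end` | 450, 1290 | min since midnight | The 07:30–21:30 SVP day. |

## Matching actual to proposed times

Multiple actual voids and multiple proposed slots must be paired before
Stage 3 can count hits. `match_voids()` computes a **maximum-cardinality
one-to-one matching** under the admissibility rule &#124;actual − proposed&#124; ≤
window. One-to-one matching prevents a single void from satisfying two
slots; maximum cardinality gives staff the benefit of the doubt whenever a
consistent pairing exists. The implementation is greedy — proposed slots in
ascending order, each taking the earliest unused admissible actual — which
is optimal for symmetric-interval admissibility on a line; the test suite
verifies equality with an exhaustive search over all injective assignments
on every instance up to 5×5 built from a time grid, plus random instances.
How the original analysis paired voids is not documented; one-to-one
maximum matching is this package's choice, recorded here.

Exempted occasions are removed *with their actual time*: a justified early
or late void must not drift over to satisfy a neighbouring slot.

## Denominators and pooling

Arm-level summaries (`summarise_arm()`) follow the published table's
conventions. Stage-1 and Stage-2 rates are percentages of **all** logs in
the arm. Stage-3/4 rates are computed only over logs achieving Stages 1 and
2, and "on average, how often" is ambiguous between two estimands, so both
are implemented:

* `per_log` (default): the unweighted mean of per-log proportions — every
  patient-day weighs equally. Logs whose occasions were all exempted have an
  undefined proportion and are excluded (`n_stage3_excluded` reports the
  count).
* `pooled`: total met occasions over total assessed occasions — every
  occasion weighs equally. This is the mode with a clean closed-form
  expectation under the generator, so parameter-recovery tests use it.

Percentages are rounded **half-up to one decimal** (`percent()`), applied at
presentation; internal aggregation keeps full precision. A zero denominator
yields an undefined-value marker (`NA`, rendered "—"), never a division
error and never a fake 0. Pooling deliberately ignores the clustering of
logs within patients, sites and sampled periods, replicating the simple
descriptive analysis this design supports; no inferential statistics or
design-effect corrections are produced, and none should be read into the
output.

## Stratified period sampling

`build_strata()` splits a site's planned recruitment window into three
contiguous near-equal strata (remainder days to the last); recruitment
extensions append further strata of at most one planned-stratum length
each, so the number of sampled periods grows with the extension — matching
the observed six-to-nine-period range. The exact split and extension rules
were not documented in the trial design; near-equal-with-remainder-last and
capped extension strata are this package's reading. `sample_periods()`
draws, per stratum, one pair of non-overlapping 14-day periods **uniformly
over all admissible pairs** of start days — the neutral choice where the
original statistician's scheme is unknown, and a testable one: the suite
checks the empirical pair distribution over 10,000 seeds with a chi-square
test at α = 0.01 against exact enumeration. Draws are seed-reproducible and
leave the caller's RNG state untouched.

## The synthetic-log generator

`generate_fleet()` emulates the documentation behaviour the assessment must
withstand, one log per patient-day across two trial arms:

1. **Interval documentation**: blank with `p_interval_missing` (0.10),
   a range with `p_interval_range` (0.06), otherwise a single value drawn
   from `interval_choices` (defaults 2-, 2.5-, 3-hourly with probabilities
   0.50/0.25/0.25, mean 2.4 h — intervals in practice were almost always
   between 2- and 3-hourly).
2. **Schedule**: laid from 07:30 at the interval up to 21:30. With
   `p_schedule_miscalc` (0.35) every gap is shrunk by 60 minutes — the
   canonical "3-hourly interval scheduled 2-hourly" error, severity fixed
   for determinism. Each *interior* slot is then blanked with
   `p_schedule_gap` (0.08); endpoints are never blanked, so the
   between-first-and-last completeness rule is exactly what catches it.
3. **Actual voids**: present per slot with 1 − `p_void_missing` (0.40
   missing), at proposed + Gaussian(0, `timing_sd_minutes` = 20) rounded to
   the minute and clipped to the day window. Gaussian is the simplest
   symmetric deviation model and keeps the Stage-3 expectation analytic.
4. **Exemptions and answers**: occasions missing a void or outside the
   30-minute leeway receive a justification code with `p_exempt_comment`
   (0.10); best-practice answers are yes/missing/no per the configured
   probabilities (0.58/0.25 encouragement, 0.60/0.25 asked-if-wet).

The default rates were chosen once to make the default fleet resemble the
fidelity levels reported for this kind of programme — Stage-1 rate in the
mid-80s %, Stage-2 around 35–40 % of all logs, Stage-3 near 55 %,
best-practice rates near 60 % — while each remains an independent dial.

`expected_summaries()` returns the closed-form expectations: Stage-1 pass =
1 − p_missing − p_range; Stage-2 pass given Stage 1 averages
(1 − p_miscalc)·(1 − p_gap)^(interior slots) over the interval mix (the
miscalculation factor applies only where shrinking leaves a positive gap);
Stage-3 and Stage-4 rates are the configured per-occasion probabilities.
The Stage-3 timing term accounts for **clipping**: a slot proposed at the
window boundary (07:30 is always one) can only deviate inwards, so its hit
probability is Φ(w/σ) rather than 2Φ(w/σ) − 1; interior slots sit at
2Φ(30/20) − 1 ≈ 0.8664. Parameter-recovery tests run a 5,000-log fleet
through the full pipeline and require every summary statistic within three
standard errors of its expectation; matching-oracle enumeration uses 6-value
time grids up to 5×5; sampler uniformity uses 10,000 seeds on an 84-day
stratum. These sizes make all three-standard-error bounds computable and
discriminating.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: schedules that genuinely start late or stop early
(simulated schedules always span the full day, so the simulated mean number
of proposed times, ≈ 6.6, is higher than the ≈ 5 seen in practice);
weekday/weekend staffing patterns; correlation of errors within staff,
wards or days; handwriting/OCR noise; informative missingness beyond the
yes-bias already built into the answer model; and patients starting or
stopping the programme mid-window. Conclusions about real fidelity levels
require real logs; the simulator validates the *machinery*, not the ward.

## Numerical and degenerate-input choices

* Times are integer minutes since midnight; "HH:MM" 24-hour text at the
  boundary. Malformed times degrade to *absent* with a load-report warning,
  never an exception; only a structurally missing CSV column errors.
* A log with zero events survives CSV round-trip via a placeholder row;
  missing answers round-trip as missing.
* All-exempt logs are defined (0 met of 0 assessed) at the log level and
  excluded from per-log averaging at the arm level.
* Half-up rounding uses a machine-epsilon nudge so exact halves round up
  despite binary floating point.
* Seeded operations (`generate_fleet()`, `sample_periods()`) restore the
  caller's RNG state on exit.

## Known limitations

* Exemption semantics are code-membership only; the package cannot judge
  whether a justification was clinically appropriate, and any code on an
  occasion exempts it whether or not that occasion was actually missed.
* The staged filter is all-or-nothing at Stages 1–2: a log with a single
  wrong gap contributes nothing to Stage 3, so substantial partial fidelity
  is invisible — a property inherited from the method itself, worth
  revisiting if degrees of fidelity are wanted.
* Arm summaries are descriptive; standard errors would require modelling
  the two-level clustering the pooling discards.
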