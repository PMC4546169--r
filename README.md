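# svpfidelity

Treatment-fidelity assessment for systematic voiding programmes (SVPs),
built around daily clinical logs.

## The problem

A systematic voiding programme is a conservative continence intervention
(bladder training or prompted voiding) delivered on the ward as a daily
schedule of toileting times. Each patient-day is documented on a clinical
log: a prescribed **voiding interval** (e.g. "2-hourly" = 120 minutes), a
schedule of **proposed voiding times** written at the start of the day
(07:30–21:30), the **actual voiding times** recorded after each void, and
yes/no answers to best-practice questions (giving encouragement; on prompted
voiding, asking whether the patient was wet).

In trials of such programmes, fidelity to treatment delivery is measured
from these logs — but real logs are messy: intervals are left blank or
written as ranges ("2 – 3 hourly"), scheduled times go missing, and gaps are
miscalculated (a 3-hourly interval scheduled at 8 am, 10 am, 12 pm). A
direct comparison of actual against proposed times is then meaningless.
`svpfidelity` implements the staged *key quality indicator* (KQI) approach
that handles this: each log is filtered through prerequisite checks before
adherence is scored, and assessment terminates at the first failed
prerequisite.

| Stage | Key quality indicator |
|---|---|
| 1 | Voiding interval present and documented as a single number |
| 2 | Proposed times complete between endpoints, every gap identical to the interval |
| 3 | Per proposed time: actual void documented within ±30 min (clinically justified occasions exempted) |
| 4a | Per proposed time: encouragement documented "yes" |
| 4b | Per proposed time: asked-if-wet documented "yes" (prompted voiding only) |

Stage 3 uses a maximum-cardinality one-to-one matching between proposed and
actual times with an inclusive |Δ| ≤ 30 min window, so a single void cannot
satisfy two slots. Results pool per trial arm into the standard report row
set: stage pass rates (% of all logs for Stages 1–2; % of occasions over
Stage-1-and-2 passers for Stages 3–4), the mean voiding interval and mean
schedule length, and the interval distribution among passers.

The package also provides:

* **Stratified period sampling** (`build_strata()`, `sample_periods()`,
  `select_logs()`): splits a site's planned recruitment window into three
  near-equal strata (plus extension strata), draws two non-overlapping
  14-day audit periods per stratum uniformly over all admissible pairs, and
  selects the logs they cover.
* **A synthetic-log generator** (`simulation_config()`, `generate_fleet()`)
  with configurable rates of every observed failure mode — missing/range
  intervals, schedule gaps, miscalculated gaps, Gaussian timing deviation,
  missing voids, justified exemptions, missing answers — plus closed-form
  expectations (`expected_summaries()`) so the whole pipeline is testable
  without trial data.

## Worked example

Score a single log, then summarise a simulated arm:

```r
library(svpfidelity)

log <- clinical_log(
  log_id = "L001", patient_id = "P01", site_id = "INT01",
  arm = "intervention", date = "2011-03-14", regime = "prompted_voiding",
  interval_text = "2-hourly",
  events = voiding_events(
    proposed_time = parse_time_of_day(c("07:30", "09:30", "11:30", "13:30")),
    actual_time   = parse_time_of_day(c("07:42", NA,      "11:25", "14:15")),
    encouragement = c("yes", NA, "yes", "no"),
    wet_asked     = c("yes", "yes", NA, "yes"),
    justification_code = c(NA, "OFF_WARD", NA, NA)
  )
)
assess_log(log)
#> <kqi_result L001> terminal stage: complete
#>   stage 3: 2/3 met (4 proposed, 1 exempted)
```

The interval is a valid single number (Stage 1) and the schedule is
complete with exact 120-minute gaps (Stage 2). Of the four proposed times,
the 09:30 slot has a justified absence (`OFF_WARD`) and is exempted; 07:42
and 11:25 fall within the 30-minute leeway; 14:15 is 45 minutes late, so 2
of 3 assessed occasions are met.

```r
fleet <- generate_fleet(simulation_config(seed = 1))
arms <- vapply(fleet, function(l) l$arm, character(1))
logs <- fleet[arms == "intervention"]
summarise_arm(assess_fleet(logs), logs, total_enrolled = 164)
#> arm: intervention   n_logs: 400   n_patients: 40
#> pct_of_total_patients: 24.4   pct_pv: 87.5   pct_bt: 12.5
#> stage1_pct: 84.5   stage2_pct: 38.3   n_pass12: 153
#> stage3_pct: 55.5   stage4a_pct: 58.9   stage4b_pct: 60.8
#> mean_interval_hours: 2.42   mean_n_proposed: 6.63
```

Under the default error rates, 84.5 % of logs have a valid interval, 38.3 %
also have a correct schedule (153 logs), and on those logs an actual void
fell within 30 minutes of its proposed time on 55.5 % of assessed occasions.
`interval_distribution()` and `plot_interval_distribution()` give the
interval histogram over the 153 passers; `write_report()` emits the JSON and
CSV report.

A thin command-line front end over the same functions lives at
`inst/cli/svpfidelity.R` (`simulate`, `assess`, `sample` subcommands).

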