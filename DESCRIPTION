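Package: svpfidelity
Title: Fidelity Assessment for Systematic Voiding Programme Clinical Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing fidelity to treatment delivery of a
    systematic voiding programme (SVP) from daily clinical logs. Parses
    per-patient per-day logs (voiding interval, schedule of proposed
    voiding times, actual voiding events, best-practice answers), scores
    each log against staged key quality indicators (interval validity,
    schedule correctness, 30-minute void-time adherence with clinically
    justifiable exemptions, best-practice documentation), pools results
    into trial-arm summaries, draws stratified 14-day audit periods from
    a recruitment window, and simulates realistic log fleets with
    configurable documentation-error and timing-deviation processes so
    the whole pipeline can be exercised without trial data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
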