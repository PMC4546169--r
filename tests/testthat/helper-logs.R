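# Shared fixture builders and the brute-force matching oracle.

# Quick log builder: times as "HH:MM" strings; events aligned by position.
make_log <- function(interval_text, proposed = character(), actual = NULL,
                     encouragement = NA, wet_asked = NA,
                     justification_code = NA,
                     regime = "prompted_voiding", arm = "intervention",
                     log_id = "L1", patient_id = "P1", site_id = "S1",
                     date = "2011-03-01", validate = TRUE) {
  n <- max(length(proposed), length(actual %||% character()))
  pad <- function(x, fill = NA_character_) {
    if (is.null(x)) rep(fill, n) else c(x, rep(fill, n - length(x)))
  }
  ev <- voiding_events(
    proposed_time = parse_time_of_day(pad(proposed)),
    actual_time = parse_time_of_day(pad(actual)),
    encouragement = pad(if (length(encouragement) == 1 && is.na(encouragement)) NULL else encouragement),
    wet_asked = if (regime == "bladder_training") {
      rep("not_applicable", n)
    } else {
      pad(if (length(wet_asked) == 1 && is.na(wet_asked)) NULL else wet_asked)
    },
    justification_code = pad(if (length(justification_code) == 1 && is.na(justification_code)) NULL else justification_code)
  )
  clinical_log(
    log_id = log_id, patient_id = patient_id, site_id = site_id, arm = arm,
    date = date, regime = regime, interval_text = interval_text, events = ev,
    validate = validate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle for match_voids(): exhaustive search over injective
# assignments of proposed slots to actual times.
oracle_match_count <- function(proposed, actual, window) {
  recurse <- function(i, used) {
    if (i > length(proposed)) {
      return(0L)
    }
    best <- recurse(i + 1L, used) # leave slot i unmatched
    ok <- which(!used & abs(actual - proposed[i]) <= window)
    for (j in ok) {
      used[j] <- TRUE
      best <- max(best, 1L + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  recurse(1L, rep(FALSE, length(actual)))
}

expect_logs_equal <- function(got, want) {
  expect_length(got, length(want))
  for (i in seq_along(want)) {
    for (f in c("log_id", "patient_id", "site_id", "arm", "regime")) {
      expect_identical(got[[i]][[f]], want[[i]][[f]])
    }
    expect_equal(got[[i]]$date, want[[i]]$date)
    expect_equal(got[[i]]$interval, want[[i]]$interval)
    expect_equal(as.data.frame(got[[i]]$events), as.data.frame(want[[i]]$events))
  }
}

# Small fleet used across suites; cached so each file pays the cost once.
test_fleet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        n_sites_per_arm = 2L, n_patients_per_site = 8L,
        days_per_patient = 6L, seed = 424242L
      )
      cache <<- generate_fleet(cfg)
    }
    cache
  }
})
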