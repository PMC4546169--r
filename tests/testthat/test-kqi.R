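test_that("Stage 1 accepts only a single documented interval", {
  expect_true(assess_stage1(make_log("2-hourly", proposed = c("07:30", "09:30"))))
  expect_false(assess_stage1(make_log("2 – 3 hourly", proposed = c("07:30", "09:30"))))
  expect_false(assess_stage1(make_log("", proposed = c("07:30", "09:30"))))
  expect_false(assess_stage1(make_log("whenever", proposed = c("07:30", "09:30"))))
})

test_that("Stage 2 verifies schedule completeness and gap correctness", {
  # the classic miscalculation: 3-hour interval, 2-hour gaps
  bad <- make_log("3-hourly", proposed = c("08:00", "10:00", "12:00"))
  s2 <- assess_stage2(bad)
  expect_false(s2$passed)
  expect_equal(s2$failure_reasons, "interval_mismatch")

  good <- make_log("2-hourly", proposed = c(
    "07:30", "09:30", "11:30", "13:30", "15:30", "17:30", "19:30", "21:30"
  ))
  s2 <- assess_stage2(good)
  expect_true(s2$passed)
  expect_equal(s2$span_shortfall_minutes, 0L)

  # blank proposed_time amid the schedule
  ev <- voiding_events(
    proposed_time = c(450L, 570L, NA, 810L),
    actual_time = c(NA, NA, 700L, NA)
  )
  gap <- clinical_log("L1", "P1", "S1", "intervention", "2011-03-01",
                      "prompted_voiding", "2-hourly", events = ev)
  s2 <- assess_stage2(gap)
  expect_false(s2$passed)
  expect_true("gap_in_schedule" %in% s2$failure_reasons)

  # a single proposed time cannot demonstrate the interval
  one <- make_log("2-hourly", proposed = "09:30")
  expect_equal(assess_stage2(one)$failure_reasons, "no_proposed_times")

  # short span does not fail, it is reported
  short <- make_log("2-hourly", proposed = c("09:30", "11:30", "13:30"))
  s2 <- assess_stage2(short)
  expect_true(s2$passed)
  expect_equal(s2$span_shortfall_minutes, (570L - 450L) + (1290L - 810L))

  # contract: Stage 2 is undefined for Stage-1 failures
  expect_error(assess_stage2(make_log("2 – 3 hourly")), "failed Stage 1")
})

test_that("gap tolerance is configurable without changing the rule", {
  wobbly <- make_log("2-hourly", proposed = c("07:30", "09:31", "11:30"))
  expect_false(assess_stage2(wobbly)$passed)
  expect_true(assess_stage2(wobbly, kqi_config(tolerance_minutes = 2))$passed)
})

test_that("match_voids is boundary-inclusive and one-to-one", {
  expect_equal(match_voids(480L, 510L, 30L), 1L)
  expect_equal(match_voids(480L, 511L, 30L), integer(0))
  expect_equal(match_voids(c(480L, 600L), 540L, 30L), integer(0))
  # one void cannot satisfy two slots
  expect_length(match_voids(c(480L, 520L), 500L, 30L), 1)
  expect_equal(match_voids(c(480L, 600L), c(505L, 610L), 30L), c(1L, 2L))
  expect_equal(match_voids(integer(), c(500L), 30L), integer(0))
})

test_that("match_voids attains the brute-force maximum matching on all small instances", {
  grid <- c(0L, 15L, 30L, 45L, 60L, 75L)
  subsets <- unlist(
    lapply(0:5, function(k) combn(grid, k, simplify = FALSE)),
    recursive = FALSE
  )
  for (window in c(15L, 30L)) {
    for (proposed in subsets) {
      for (actual in subsets) {
        expect_equal(
          length(match_voids(proposed, actual, window)),
          oracle_match_count(proposed, actual, window),
          info = sprintf(
            "p=[%s] a=[%s] w=%d", paste(proposed, collapse = ","),
            paste(actual, collapse = ","), window
          )
        )
      }
    }
  }
})

test_that("match_voids matches the oracle on random 5x5 instances", {
  set.seed(99)
  for (rep in 1:300) {
    proposed <- sort(sample(0:200, sample(0:5, 1)))
    actual <- sort(sample(0:200, sample(0:5, 1)))
    expect_equal(
      length(match_voids(proposed, actual, 30L)),
      oracle_match_count(proposed, actual, 30L)
    )
  }
})

test_that("Stage 3 exempts justified occasions from numerator and denominator", {
  log <- make_log("2-hourly",
    proposed = c("07:30", "09:30", "11:30", "13:30", "15:30"),
    actual = c("07:40", "09:35", NA, "12:55", "16:10"),
    justification_code = c(NA, NA, "OFF_WARD", NA, NA)
  )
  s3 <- assess_stage3(log)
  expect_equal(s3$n_proposed, 5L)
  expect_equal(s3$n_exempted, 1L)
  expect_equal(s3$n_assessed, 4L)
  expect_equal(s3$n_met, 2L) # 07:40 and 09:35; 12:55 and 16:10 are outside
  expect_equal(s3$n_exempted + s3$n_assessed, s3$n_proposed)

  # codes outside the configured list do not exempt
  s3b <- assess_stage3(log, kqi_config(exemption_codes = "OTHER"))
  expect_equal(s3b$n_assessed, 5L)

  # all slots exempted: defined, degenerate
  all_ex <- make_log("2-hourly",
    proposed = c("07:30", "09:30"),
    justification_code = c("ASLEEP", "ASLEEP")
  )
  s3c <- assess_stage3(all_ex)
  expect_equal(s3c$n_assessed, 0L)
  expect_equal(s3c$n_met, 0L)

  expect_error(assess_stage3(make_log("3-hourly", proposed = c("08:00", "10:00"))),
               "failed Stage 2")
})

test_that("an actual void on an exempted occasion is removed with it", {
  log <- make_log("2-hourly",
    proposed = c("07:30", "09:30"),
    actual = c("08:30", NA), # 60 min late: miss, justified
    justification_code = c("MEDICAL", NA)
  )
  s3 <- assess_stage3(log)
  # the stray 08:30 must not drift over to satisfy the 09:30 slot
  expect_equal(s3$n_assessed, 1L)
  expect_equal(s3$n_met, 0L)
})

test_that("Stage 4 counts literal yes answers over proposed voiding times", {
  log <- make_log("2-hourly",
    proposed = c("07:30", "09:30", "11:30", "13:30", "15:30", "17:30"),
    encouragement = c("yes", "yes", NA, "no", "yes", "yes"),
    wet_asked = c("yes", NA, NA, "no", "yes", "yes")
  )
  s4 <- assess_stage4(log)
  expect_equal(s4$stage4a_yes, 4L)
  expect_equal(s4$stage4a_n, 6L)
  expect_equal(s4$stage4b_yes, 3L)
  expect_equal(s4$stage4b_n, 6L)

  bt <- make_log("2-hourly",
    proposed = c("07:30", "09:30"),
    encouragement = c("yes", "yes"),
    regime = "bladder_training"
  )
  s4bt <- assess_stage4(bt)
  expect_equal(s4bt$stage4a_yes, 2L)
  expect_true(is.na(s4bt$stage4b_n))

  all_yes <- make_log("2-hourly",
    proposed = c("07:30", "09:30"),
    encouragement = c("yes", "yes"), wet_asked = c("yes", "yes")
  )
  s4c <- assess_stage4(all_yes)
  expect_equal(s4c$stage4a_yes, s4c$stage4a_n)
})

test_that("assess_log terminates at the first failed stage", {
  r1 <- assess_log(make_log("2 – 3 hourly", proposed = c("08:00", "10:00")))
  expect_equal(r1$terminal_stage, "1")
  expect_false(r1$stage1_pass)
  expect_null(r1$stage2)
  expect_null(r1$stage3)
  expect_true(is.na(r1$stage4a_n))

  r2 <- assess_log(make_log("3-hourly", proposed = c("08:00", "10:00", "12:00")))
  expect_equal(r2$terminal_stage, "2")
  expect_true(r2$stage1_pass)
  expect_false(r2$stage2$passed)
  expect_null(r2$stage3)

  full <- make_log("2-hourly",
    proposed = c("07:30", "09:30", "11:30"),
    actual = c("07:31", "09:29", "11:45"),
    encouragement = c("yes", "yes", "no"),
    wet_asked = c("yes", NA, "yes")
  )
  r3 <- assess_log(full)
  expect_equal(r3$terminal_stage, "complete")
  expect_equal(r3$stage3$n_met, 3L)
  expect_equal(r3$stage4a_yes, 2L)
  expect_equal(r3$stage4b_yes, 2L)
})

test_that("identical logs assess identically", {
  log <- test_fleet()[[5]]
  expect_identical(assess_log(log), assess_log(log))
})

test_that("kqi config round-trips through YAML and JSON", {
  cfg <- kqi_config(window_minutes = 20, exemption_codes = c("A", "B"))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), ypath)
  expect_equal(read_kqi_config(ypath), cfg)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), jpath, auto_unbox = TRUE)
  expect_equal(read_kqi_config(jpath), cfg)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(window_mins = 10), bad)
  expect_error(read_kqi_config(bad), "unknown config key")
})
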