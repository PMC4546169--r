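test_that("percent rounds half-up to one decimal and never divides by zero", {
  expect_equal(percent(40, 164), 24.4)
  expect_equal(percent(31, 125), 24.8)
  expect_equal(percent(154, 396), 38.9) # 38.888...
  expect_equal(percent(102, 320), 31.9) # 31.875 rounds up
  expect_equal(percent(0, 10), 0.0)
  expect_equal(percent(1, 8), 12.5)
  expect_equal(percent(1, 3), 33.3)
  expect_true(is.na(percent(3, 0)))
  expect_equal(percent(c(40, 31), c(164, 125)), c(24.4, 24.8))
})

test_that("complements of percent sum to 100 within one final-digit ulp", {
  set.seed(1)
  for (i in 1:200) {
    b <- sample(1:500, 1)
    a <- sample(0:b, 1)
    expect_lte(abs(percent(a, b) + percent(b - a, b) - 100), 0.1 + 1e-9)
  }
})

make_example_arm <- function() {
  logs <- list(
    make_log("", proposed = c("08:00", "10:00"), log_id = "A", patient_id = "p1"),
    make_log("2 – 3 hourly", proposed = c("08:00", "10:00"), log_id = "B", patient_id = "p1"),
    make_log("3-hourly", proposed = c("08:00", "10:00", "12:00"), log_id = "C", patient_id = "p2"),
    make_log("2-hourly",
      proposed = c("07:30", "09:30", "11:30", "13:30"),
      actual = c("07:35", "09:40", NA, "13:31"),
      encouragement = c("yes", "no", "yes", NA),
      wet_asked = c("yes", "yes", "yes", "yes"),
      log_id = "D", patient_id = "p2"
    )
  )
  list(logs = logs, results = assess_fleet(logs))
}

test_that("summarise_arm applies the staged denominator conventions", {
  ex <- make_example_arm()
  s <- summarise_arm(ex$results, ex$logs, total_enrolled = 8)
  expect_equal(s$n_logs, 4L)
  expect_equal(s$n_patients, 2L)
  expect_equal(s$pct_of_total_patients, 25.0)
  expect_equal(s$stage1_pct, 50.0) # C and D of 4 logs
  expect_equal(s$stage2_pct, 25.0) # only D, out of ALL logs
  expect_equal(s$n_pass12, 1L)
  expect_equal(s$stage3_pct, 75.0) # 3 of 4 slots in D
  expect_equal(s$stage4a_pct, 50.0)
  expect_equal(s$stage4b_pct, 100.0)
  expect_equal(s$mean_interval_hours, 2)
  expect_equal(s$mean_n_proposed, 4)
  expect_equal(s$pct_pv + s$pct_bt, 100.0)
})

test_that("per-log and pooled Stage-3 modes diverge as documented", {
  logs <- list(
    make_log("2-hourly",
      proposed = c("07:30", "09:30"), actual = c("07:30", "09:30"),
      log_id = "A", patient_id = "p1"
    ), # 2/2
    make_log("2-hourly",
      proposed = c("07:30", "09:30", "11:30", "13:30"),
      actual = c("07:30", "09:30", NA, NA),
      log_id = "B", patient_id = "p2"
    ) # 2/4
  )
  results <- assess_fleet(logs)
  per_log <- summarise_arm(results, logs, stage_mode = "per_log")
  pooled <- summarise_arm(results, logs, stage_mode = "pooled")
  expect_equal(per_log$stage3_pct, 75.0) # mean(1, 0.5)
  expect_equal(pooled$stage3_pct, 66.7) # 4/6 occasions
  # mean-of-logs lies within the per-log proportions
  expect_gte(per_log$stage3_pct, 50)
  expect_lte(per_log$stage3_pct, 100)
})

test_that("logs with all occasions exempted drop out of the Stage-3 average", {
  logs <- list(
    make_log("2-hourly",
      proposed = c("07:30", "09:30"), actual = c("07:30", "09:30"),
      log_id = "A", patient_id = "p1"
    ),
    make_log("2-hourly",
      proposed = c("07:30", "09:30"),
      justification_code = c("ASLEEP", "OFF_WARD"),
      log_id = "B", patient_id = "p2"
    )
  )
  results <- assess_fleet(logs)
  s <- summarise_arm(results, logs)
  expect_equal(s$n_stage3_excluded, 1L)
  expect_equal(s$stage3_pct, 100.0)
})

test_that("empty input yields the empty-summary marker, not an error", {
  s <- summarise_arm(list(), list())
  expect_equal(s$n_logs, 0L)
  expect_true(is.na(s$stage1_pct))
})

test_that("interval distribution covers exactly the Stage-1-and-2 passers", {
  ex <- make_example_arm()
  dist <- interval_distribution(ex$results, ex$logs)
  expect_equal(dist$interval_minutes, 120L)
  expect_equal(dist$n, 1L)

  fleet <- test_fleet()
  results <- assess_fleet(fleet)
  s_int <- summarise_arm(
    results[logs_tbl(fleet)$arm == "intervention"],
    fleet[logs_tbl(fleet)$arm == "intervention"]
  )
  d_int <- interval_distribution(
    results[logs_tbl(fleet)$arm == "intervention"],
    fleet[logs_tbl(fleet)$arm == "intervention"]
  )
  expect_equal(sum(d_int$n), s_int$n_pass12)
  expect_setequal(d_int$interval_minutes, intersect(c(120L, 150L, 180L), d_int$interval_minutes))
})

test_that("write_report emits JSON that parses back and a table with em dashes", {
  fleet <- test_fleet()
  arm <- logs_tbl(fleet)$arm
  summaries <- dplyr::bind_rows(lapply(unique(arm), function(a) {
    summarise_arm(assess_fleet(fleet[arm == a]), fleet[arm == a],
                  total_enrolled = 164)
  }))
  dists <- lapply(
    stats::setNames(unique(arm), unique(arm)),
    function(a) interval_distribution(assess_fleet(fleet[arm == a]), fleet[arm == a])
  )
  json_path <- withr::local_tempfile(fileext = ".json")
  write_report(summaries, dists, json_path)
  back <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(back$arms$stage1_pct, summaries$stage1_pct)
  expect_equal(back$arms$n_pass12, summaries$n_pass12)

  csv_path <- sub("\\.json$", ".csv", json_path)
  table <- readr::read_csv(csv_path, show_col_types = FALSE)
  expect_equal(ncol(table), nrow(summaries) + 1)

  # undefined values render as an em dash, not zero
  empty <- summarise_arm(
    assess_fleet(list(make_log("2 – 3 hourly", proposed = c("08:00", "10:00")))),
    list(make_log("2 – 3 hourly", proposed = c("08:00", "10:00")))
  )
  write_report(empty, NULL, json_path)
  table <- readr::read_csv(csv_path, show_col_types = FALSE)
  expect_true("—" %in% table$intervention)
})

test_that("plot_interval_distribution returns a bar chart", {
  ex <- make_example_arm()
  p <- plot_interval_distribution(interval_distribution(ex$results, ex$logs))
  expect_s3_class(p, "ggplot")
})
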