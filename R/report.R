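#' Percentage with half-up rounding to one decimal
#'
#' The reporting convention throughout: `100 * numerator / denominator`,
#' rounded half-up to one decimal place (so 24.45 prints 24.5, unlike R's
#' banker's rounding). A zero denominator yields `NA`, the undefined-value
#' marker, never an error; renderers show it as an em dash.
#'
#' @param numerator,denominator Counts (vectorised).
#' @return Numeric percent in \[0, 100\] or `NA`.
#' @examples
#' percent(40, 164) # 24.4
#' percent(154, 396) # 38.9
#' @export
percent <- function(numerator, denominator) {
  ifelse(denominator > 0,
    round_half_up(100 * numerator / denominator, 1),
    NA_real_
  )
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge past binary representation error so .5 always rounds up
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Pool KQI results into a trial-arm summary
#'
#' Reproduces the arm-level fidelity table: log and patient counts, regime
#' mix, stage pass rates and, for logs that achieved Stages 1 and 2, the
#' Stage-3/4 adherence percentages plus the mean voiding interval and mean
#' schedule length.
#'
#' Denominator conventions: `stage1_pct` and `stage2_pct` are percentages of
#' *all* logs in the arm (`stage2_pct` counts logs achieving both stages, so
#' it is not conditional on Stage 1). Stage-3/4 percentages are computed only
#' over Stage-1-and-2 passers, in one of two modes: `"per_log"` (default)
#' averages each log's proportion, weighting every patient-day equally;
#' `"pooled"` divides total met occasions by total assessed occasions. The
#' two differ whenever logs have different numbers of occasions. Logs with
#' no assessable Stage-3 occasions (all exempted) have an undefined
#' proportion and are excluded from the per-log average; `n_stage3_excluded`
#' reports how many.
#'
#' @param results List of `kqi_result` objects for one arm.
#' @param logs The matching list of [clinical_log()] objects (same order or
#'   at least the same `log_id`s).
#' @param total_enrolled Total patients enrolled in the arm, for the
#'   percentage-of-patients row; `NA` to skip.
#' @param stage_mode `"per_log"` or `"pooled"`.
#' @return A one-row `arm_summary` tibble.
#' @export
summarise_arm <- function(results, logs, total_enrolled = NA_integer_,
                          stage_mode = c("per_log", "pooled")) {
  stage_mode <- match.arg(stage_mode)
  ktbl <- kqi_tbl(results)
  ltbl <- logs_tbl(logs)
  if (nrow(ktbl) == 0 || nrow(ltbl) == 0) {
    return(empty_arm_summary())
  }
  if (!setequal(ktbl$log_id, ltbl$log_id)) {
    stop("results and logs do not describe the same set of log_ids")
  }
  d <- dplyr::left_join(
    ktbl,
    ltbl[, c("log_id", "regime", "arm", "patient_id", "interval_minutes")],
    by = c("log_id", "regime")
  )
  arm <- unique(d$arm)
  if (length(arm) != 1) {
    stop("summarise_arm() expects logs from a single arm; got: ",
         paste(arm, collapse = ", "))
  }

  n_logs <- nrow(d)
  pass12 <- d[!is.na(d$stage2_pass) & d$stage2_pass, , drop = FALSE]

  stage_pct <- function(yes, n) {
    ok <- !is.na(n) & n > 0
    if (stage_mode == "per_log") {
      if (!any(ok)) NA_real_ else round_half_up(mean(100 * yes[ok] / n[ok]), 1)
    } else {
      percent(sum(yes[ok]), sum(n[ok]))
    }
  }
  pv <- pass12[pass12$regime == "prompted_voiding", , drop = FALSE]

  tibble::tibble(
    arm = arm,
    n_logs = n_logs,
    n_patients = dplyr::n_distinct(d$patient_id),
    pct_of_total_patients = percent(dplyr::n_distinct(d$patient_id), total_enrolled),
    pct_pv = percent(sum(d$regime == "prompted_voiding"), n_logs),
    pct_bt = percent(sum(d$regime == "bladder_training"), n_logs),
    stage1_pct = percent(sum(d$stage1_pass), n_logs),
    stage2_pct = percent(nrow(pass12), n_logs),
    n_pass12 = nrow(pass12),
    stage3_pct = stage_pct(pass12$n_met, pass12$n_assessed),
    n_stage3_excluded = sum(pass12$n_assessed == 0),
    stage4a_pct = stage_pct(pass12$stage4a_yes, pass12$stage4a_n),
    stage4b_pct = stage_pct(pv$stage4b_yes, pv$stage4b_n),
    mean_interval_hours = if (nrow(pass12) == 0) {
      NA_real_
    } else {
      mean(pass12$interval_minutes) / 60
    },
    mean_n_proposed = if (nrow(pass12) == 0) NA_real_ else mean(pass12$n_proposed),
    stage_mode = stage_mode
  )
}

empty_arm_summary <- function() {
  tibble::tibble(
    arm = NA_character_, n_logs = 0L, n_patients = 0L,
    pct_of_total_patients = NA_real_, pct_pv = NA_real_, pct_bt = NA_real_,
    stage1_pct = NA_real_, stage2_pct = NA_real_, n_pass12 = 0L,
    stage3_pct = NA_real_, n_stage3_excluded = 0L,
    stage4a_pct = NA_real_, stage4b_pct = NA_real_,
    mean_interval_hours = NA_real_, mean_n_proposed = NA_real_,
    stage_mode = NA_character_
  )
}

#' Voiding-interval distribution among Stage-1-and-2 passers
#'
#' Histogram of prescribed voiding intervals, restricted to clinical logs
#' that achieved Stages 1 and 2 (only those have a verified single interval
#' and correct schedule). Counts sum to `n_pass12` of [summarise_arm()].
#'
#' @inheritParams summarise_arm
#' @return Tibble with `interval_minutes`, `interval_hours` and `n`.
#' @export
interval_distribution <- function(results, logs) {
  ktbl <- kqi_tbl(results)
  ltbl <- logs_tbl(logs)
  d <- dplyr::left_join(
    ktbl, ltbl[, c("log_id", "regime", "interval_minutes")],
    by = c("log_id", "regime")
  )
  d <- d[!is.na(d$stage2_pass) & d$stage2_pass, , drop = FALSE]
  out <- dplyr::count(d, interval_minutes = .data$interval_minutes)
  out$interval_hours <- out$interval_minutes / 60
  out[, c("interval_minutes", "interval_hours", "n")]
}

#' Bar chart of the voiding-interval distribution
#'
#' @param dist Output of [interval_distribution()], optionally with an added
#'   `arm` column to facet by arm.
#' @return A ggplot object.
#' @export
plot_interval_distribution <- function(dist) {
  p <- ggplot2::ggplot(
    dist,
    ggplot2::aes(x = factor(.data$interval_hours), y = .data$n)
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "Voiding interval (hours)",
      y = "Clinical logs (Stages 1 and 2 achieved)"
    ) +
    ggplot2::theme_minimal()
  if ("arm" %in% names(dist)) {
    p <- p + ggplot2::facet_wrap(~arm)
  }
  p
}

#' Write the fidelity report
#'
#' Emits a machine-readable JSON report and a human-readable CSV table with
#' one column per trial arm, rows in the standard order (log/patient counts,
#' regime mix, stage rates, interval summaries). Undefined values render as
#' an em dash in the table, never as 0.
#'
#' @param summaries Tibble of [summarise_arm()] rows (one per arm).
#' @param distributions Named list of [interval_distribution()] tibbles,
#'   names matching `summaries$arm`; may be `NULL`.
#' @param json_path Output path for the JSON report.
#' @param csv_path Output path for the table; defaults to `json_path` with a
#'   `.csv` extension.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(summaries, distributions = NULL, json_path,
                         csv_path = sub("\\.json$", ".csv", json_path)) {
  if (identical(csv_path, json_path)) csv_path <- paste0(json_path, ".csv")
  payload <- list(
    arms = summaries,
    interval_distributions = distributions
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  fmt <- function(x) {
    ifelse(is.na(x), "—", format(x, trim = TRUE, digits = 4))
  }
  rows <- c(
    n_logs = "Number of clinical logs analysed",
    n_patients = "Number of patients",
    pct_of_total_patients = "Percentage of total number of patients",
    pct_pv = "% prompted voiding",
    pct_bt = "% bladder training",
    stage1_pct = "STAGE 1: % with voiding interval present and correctly documented",
    stage2_pct = "STAGE 2: % with interval and schedule present and correct",
    n_pass12 = "No. of clinical logs that achieved both Stage 1 and Stage 2",
    stage3_pct = "STAGE 3: % of occasions with actual void within the leeway window",
    stage4a_pct = "STAGE 4a: % of occasions encouragement documented as given",
    stage4b_pct = "STAGE 4b: % of occasions patient asked if wet (prompted voiding)",
    mean_interval_hours = "Mean voiding interval (hours)",
    mean_n_proposed = "Mean number of proposed voiding times per log"
  )
  table <- tibble::tibble(row = unname(rows))
  for (i in seq_len(nrow(summaries))) {
    table[[summaries$arm[i]]] <- vapply(
      names(rows), function(f) fmt(summaries[[f]][i]), character(1)
    )
  }
  readr::write_csv(table, csv_path)
  invisible(json_path)
}
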