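#' Assessment configuration
#'
#' Parameters of the staged key-quality-indicator (KQI) assessment.
#'
#' @param window_minutes Leeway either side of a proposed voiding time within
#'   which an actual void counts as adherent. The SVP's agreed leeway is 30
#'   minutes, applied inclusively (a deviation of exactly 30 minutes counts).
#' @param tolerance_minutes Tolerance, in minutes, when checking that gaps
#'   between consecutive proposed times equal the voiding interval. The
#'   quality indicator demands identical gaps, so the default is 0; a small
#'   tolerance can absorb transcription slop without changing the rule.
#' @param exemption_codes Justification codes that mark an occasion as
#'   clinically justifiable (e.g. patient off the ward); such occasions are
#'   removed from Stage-3 scoring entirely. The criteria themselves live in
#'   trial documents, so the codes are configuration, not behaviour.
#' @param day_start,day_end SVP day window, minutes since midnight
#'   (07:30--21:30 by default).
#' @return A list of class `kqi_config`.
#' @export
kqi_config <- function(window_minutes = 30L,
                       tolerance_minutes = 0L,
                       exemption_codes = DEFAULT_EXEMPTION_CODES,
                       day_start = DAY_START,
                       day_end = DAY_END) {
  stopifnot(window_minutes >= 0, tolerance_minutes >= 0, day_start < day_end)
  structure(
    list(
      window_minutes = as.integer(window_minutes),
      tolerance_minutes = as.integer(tolerance_minutes),
      exemption_codes = as.character(exemption_codes),
      day_start = as.integer(day_start),
      day_end = as.integer(day_end)
    ),
    class = "kqi_config"
  )
}

#' Default clinically-justifiable exemption codes
#'
#' Placeholder vocabulary for justification codes; real deployments supply
#' their own list via [kqi_config()] or a YAML/JSON config file.
#' @export
DEFAULT_EXEMPTION_CODES <- c("OFF_WARD", "ASLEEP", "REFUSED", "MEDICAL")

#' Read a `kqi_config` from YAML or JSON
#'
#' Recognised keys: `window_minutes`, `tolerance_minutes`,
#' `exemption_codes`, `day_start`, `day_end`; omitted keys keep their
#' defaults.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A [kqi_config()].
#' @export
read_kqi_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(kqi_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(kqi_config, vals)
}

#' Stage 1: is the voiding interval present and appropriately documented?
#'
#' Appropriate documentation is a single number (such as "2-hourly"), not a
#' range and not blank: without a single interval the schedule cannot be
#' checked and the log is not examined further.
#'
#' @param log A [clinical_log()].
#' @return `TRUE` iff the interval parsed as a single value.
#' @export
assess_stage1 <- function(log) {
  log$interval$status == "single"
}

#' Stage 2: are proposed voiding times present and documented correctly?
#'
#' Three ways to fail, reported as `failure_reasons`:
#' * `no_proposed_times` — fewer than two proposed times, so no interval
#'   between times exists to verify;
#' * `gap_in_schedule` — a missing entry between the first and last
#'   documented proposed time (an event row with no proposed time amid the
#'   schedule);
#' * `interval_mismatch` — a gap between consecutive proposed times that is
#'   not identical to the voiding interval (e.g. 2-hour gaps under a
#'   "3-hourly" interval).
#'
#' Schedules that start after the day window opens or stop before it closes
#' are not failed: the indicator only demands completeness between the
#' documented endpoints and correct gaps. The span shortfall is returned as
#' `span_shortfall_minutes` for monitoring instead.
#'
#' @param log A [clinical_log()] that passed Stage 1.
#' @param config A [kqi_config()].
#' @return List with `passed`, `failure_reasons` (character vector) and
#'   `span_shortfall_minutes`.
#' @export
assess_stage2 <- function(log, config = kqi_config()) {
  if (!assess_stage1(log)) {
    stop("assess_stage2() called on a log that failed Stage 1 (log ",
         log$log_id, ")")
  }
  reasons <- character()
  prop <- proposed_times(log)

  if (length(prop) < 2) {
    reasons <- c(reasons, "no_proposed_times")
  } else {
    has_prop <- !is.na(log$events$proposed_time)
    idx <- which(has_prop)
    interior <- seq(min(idx), max(idx))
    if (any(!has_prop[interior])) {
      reasons <- c(reasons, "gap_in_schedule")
    }
    gaps <- diff(prop)
    if (any(abs(gaps - log$interval$value_minutes) > config$tolerance_minutes)) {
      reasons <- c(reasons, "interval_mismatch")
    }
  }

  shortfall <- if (length(prop) == 0) {
    config$day_end - config$day_start
  } else {
    max(0L, prop[1] - config$day_start) + max(0L, config$day_end - prop[length(prop)])
  }

  list(
    passed = length(reasons) == 0,
    failure_reasons = reasons,
    span_shortfall_minutes = as.integer(shortfall)
  )
}

#' Match actual voids to proposed voiding times within a leeway window
#'
#' Finds a maximum-cardinality one-to-one matching between proposed and
#' actual times where a pair is admissible iff they differ by at most
#' `window_minutes` (inclusive). One-to-one matching stops a single void
#' from satisfying two schedule slots. The algorithm is greedy — for each
#' proposed time in ascending order, take the earliest unused admissible
#' actual time — which is maximum for interval (threshold) admissibility and
#' makes the result deterministic.
#'
#' @param proposed,actual Sorted integer vectors, minutes since midnight.
#' @param window_minutes Inclusive matching window.
#' @return Integer vector of matched indices into `proposed` (ascending).
#' @examples
#' match_voids(c(480L, 600L), c(505L, 640L), 30L)
#' @export
match_voids <- function(proposed, actual, window_minutes = 30L) {
  stopifnot(window_minutes >= 0, !is.unsorted(proposed), !is.unsorted(actual))
  matched <- integer()
  used <- rep(FALSE, length(actual))
  for (i in seq_along(proposed)) {
    ok <- which(!used & abs(actual - proposed[i]) <= window_minutes)
    if (length(ok) > 0) {
      used[ok[1]] <- TRUE
      matched <- c(matched, i)
    }
  }
  matched
}

#' Stage 3: how many proposed voiding times were met within the leeway?
#'
#' For each proposed voiding time the gold standard is an actual voiding
#' time documented within `window_minutes` of it. Occasions with a
#' clinically justifiable explanation (the event's `justification_code` is
#' in `config$exemption_codes`) are exempted: removed from both numerator
#' and denominator, together with any actual time recorded on the exempted
#' occasion. The remaining proposed times are matched one-to-one against the
#' log's remaining actual times via [match_voids()].
#'
#' @param log A [clinical_log()] that passed Stages 1 and 2.
#' @param config A [kqi_config()].
#' @return List with counts `n_proposed`, `n_exempted`, `n_assessed`
#'   (`= n_proposed - n_exempted`) and `n_met`.
#' @export
assess_stage3 <- function(log, config = kqi_config()) {
  s2 <- assess_stage2(log, config) # also enforces the Stage-1 contract
  if (!s2$passed) {
    stop("assess_stage3() called on a log that failed Stage 2 (log ",
         log$log_id, ")")
  }
  ev <- log$events
  exempt <- !is.na(ev$justification_code) &
    ev$justification_code %in% config$exemption_codes
  slot <- !is.na(ev$proposed_time)

  n_proposed <- sum(slot)
  n_exempted <- sum(slot & exempt)
  keep <- ev[!exempt, , drop = FALSE]
  matched <- match_voids(
    keep$proposed_time[!is.na(keep$proposed_time)],
    sort(keep$actual_time[!is.na(keep$actual_time)]),
    config$window_minutes
  )

  list(
    n_proposed = n_proposed,
    n_exempted = n_exempted,
    n_assessed = n_proposed - n_exempted,
    n_met = length(matched)
  )
}

#' Stage 4: best-practice documentation counts
#'
#' Over the log's proposed voiding times, counts occasions where the answer
#' literally `"yes"` was documented to (a) "Did you give encouragement?" and,
#' on prompted-voiding logs only, (b) "Did you ask the patient if they were
#' wet?". A missing answer and a documented `"no"` both count as not-yes;
#' the denominators are the number of proposed voiding times.
#'
#' @param log A [clinical_log()] that passed Stages 1 and 2.
#' @return List with `stage4a_yes`, `stage4a_n` and, for prompted voiding,
#'   `stage4b_yes`, `stage4b_n` (`NA` otherwise).
#' @export
assess_stage4 <- function(log) {
  ev <- log$events[!is.na(log$events$proposed_time), , drop = FALSE]
  n <- nrow(ev)
  out <- list(
    stage4a_yes = sum(!is.na(ev$encouragement) & ev$encouragement == "yes"),
    stage4a_n = n,
    stage4b_yes = NA_integer_,
    stage4b_n = NA_integer_
  )
  if (log$regime == "prompted_voiding") {
    out$stage4b_yes <- sum(!is.na(ev$wet_asked) & ev$wet_asked == "yes")
    out$stage4b_n <- n
  }
  out
}

#' Staged KQI assessment of one clinical log
#'
#' Runs the filtering system: Stage 1 (interval valid), Stage 2 (schedule
#' present and correct), Stage 3 (voids within the leeway window, with
#' exemptions) and Stage 4 (best-practice answers). Assessment terminates at
#' Stage 1 or Stage 2 when that stage's indicator is not achieved; later
#' stages are then not assessed and their fields are absent (`NULL`/`NA`).
#'
#' @param log A [clinical_log()].
#' @param config A [kqi_config()].
#' @return A `kqi_result`: list with `log_id`, `regime`, `stage1_pass`,
#'   `stage2`, `stage3`, `stage4a_yes`, `stage4a_n`, `stage4b_yes`,
#'   `stage4b_n` and `terminal_stage` (`"1"`, `"2"` or `"complete"`).
#' @export
assess_log <- function(log, config = kqi_config()) {
  res <- list(
    log_id = log$log_id,
    regime = log$regime,
    stage1_pass = assess_stage1(log),
    stage2 = NULL,
    stage3 = NULL,
    stage4a_yes = NA_integer_,
    stage4a_n = NA_integer_,
    stage4b_yes = NA_integer_,
    stage4b_n = NA_integer_,
    terminal_stage = "1"
  )
  if (!res$stage1_pass) {
    return(structure(res, class = "kqi_result"))
  }
  res$stage2 <- assess_stage2(log, config)
  res$terminal_stage <- "2"
  if (!res$stage2$passed) {
    return(structure(res, class = "kqi_result"))
  }
  res$stage3 <- assess_stage3(log, config)
  s4 <- assess_stage4(log)
  res[names(s4)] <- s4
  res$terminal_stage <- "complete"
  structure(res, class = "kqi_result")
}

#' @export
print.kqi_result <- function(x, ...) {
  cat(sprintf("<kqi_result %s> terminal stage: %s\n", x$log_id, x$terminal_stage))
  if (!is.null(x$stage3)) {
    cat(sprintf(
      "  stage 3: %d/%d met (%d proposed, %d exempted)\n",
      x$stage3$n_met, x$stage3$n_assessed, x$stage3$n_proposed,
      x$stage3$n_exempted
    ))
  } else if (!is.null(x$stage2)) {
    cat("  stage 2 failed:", paste(x$stage2$failure_reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assess every log in a fleet
#'
#' @param logs List of [clinical_log()] objects.
#' @param config A [kqi_config()].
#' @return List of `kqi_result` objects, aligned with `logs`.
#' @export
assess_fleet <- function(logs, config = kqi_config()) {
  lapply(logs, assess_log, config = config)
}

#' Flatten KQI results to a tibble
#'
#' One row per assessed log; list-valued stage results are expanded to
#' scalar columns (`stage2_pass`, `stage2_reasons`, `n_proposed`,
#' `n_exempted`, `n_assessed`, `n_met`, the Stage-4 counts). Absent stages
#' are `NA`.
#'
#' @param results List of `kqi_result` objects ([assess_fleet()] output).
#' @return A tibble.
#' @export
kqi_tbl <- function(results) {
  purrr::map_dfr(results, function(r) {
    tibble::tibble(
      log_id = r$log_id,
      regime = r$regime,
      stage1_pass = r$stage1_pass,
      stage2_pass = if (is.null(r$stage2)) NA else r$stage2$passed,
      stage2_reasons = if (is.null(r$stage2)) {
        NA_character_
      } else {
        paste(r$stage2$failure_reasons, collapse = ";")
      },
      n_proposed = if (is.null(r$stage3)) NA_integer_ else r$stage3$n_proposed,
      n_exempted = if (is.null(r$stage3)) NA_integer_ else r$stage3$n_exempted,
      n_assessed = if (is.null(r$stage3)) NA_integer_ else r$stage3$n_assessed,
      n_met = if (is.null(r$stage3)) NA_integer_ else r$stage3$n_met,
      stage4a_yes = r$stage4a_yes,
      stage4a_n = r$stage4a_n,
      stage4b_yes = r$stage4b_yes,
      stage4b_n = r$stage4b_n,
      terminal_stage = r$terminal_stage
    )
  })
}
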