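ARMS <- c("intervention", "supported_implementation")
REGIMES <- c("prompted_voiding", "bladder_training")
ANSWERS <- c("yes", "no")

#' Construct a daily clinical log
#'
#' One clinical log records delivery of the systematic voiding programme to
#' one patient on one day: the prescribed voiding interval, the schedule of
#' proposed voiding times written at the start of the day, the actual voiding
#' events documented by staff, and yes/no answers to the best-practice
#' questions (encouragement; for prompted voiding, asking if the patient was
#' wet). Missing answers are kept as `NA`, never coerced to `"no"` —
#' selective documentation means a blank and a "no" carry different
#' information.
#'
#' @param log_id,patient_id,site_id Identifier strings.
#' @param arm Trial arm: `"intervention"` or `"supported_implementation"`.
#' @param date Calendar date (anything `as.Date()` accepts).
#' @param regime `"prompted_voiding"` or `"bladder_training"`.
#' @param interval_text Voiding-interval text as written, parsed with
#'   [parse_interval()].
#' @param events Tibble of voiding events in log row order, with columns
#'   `proposed_time` and `actual_time` (integer minutes since midnight, `NA`
#'   when absent), `encouragement` and `wet_asked` (`"yes"`/`"no"`/`NA`;
#'   `wet_asked` is `"not_applicable"` for bladder training), `comment`
#'   (character) and `justification_code` (character, `NA` when absent).
#'   Missing columns are filled with `NA`.
#' @param validate Check invariants (default `TRUE`).
#' @return A `clinical_log` object (a list).
#' @seealso [voiding_events()] for a convenient event-table builder.
#' @export
clinical_log <- function(log_id, patient_id, site_id, arm, date, regime,
                         interval_text, events = voiding_events(),
                         validate = TRUE) {
  log <- structure(
    list(
      log_id = as.character(log_id),
      patient_id = as.character(patient_id),
      site_id = as.character(site_id),
      arm = as.character(arm),
      date = as.Date(date),
      regime = as.character(regime),
      interval = as.list(parse_interval(interval_text)[1, ]),
      events = as_event_tbl(events)
    ),
    class = "clinical_log"
  )
  if (validate) validate_clinical_log(log)
  log
}

#' Build a voiding-event table
#'
#' @param proposed_time,actual_time Integer minutes since midnight (`NA` =
#'   not documented).
#' @param encouragement,wet_asked `"yes"`, `"no"`, `NA` (missing) or, for
#'   `wet_asked` on bladder-training logs, `"not_applicable"`.
#' @param comment Free-text comment.
#' @param justification_code Code attached to a clinically justifiable
#'   explanation for an early/late/missing void, `NA` when none.
#' @return A tibble, one row per voiding event.
#' @export
voiding_events <- function(proposed_time = integer(), actual_time = NA,
                           encouragement = NA, wet_asked = NA,
                           comment = "", justification_code = NA) {
  tibble::tibble(
    proposed_time = as.integer(proposed_time),
    actual_time = as.integer(actual_time),
    encouragement = as.character(encouragement),
    wet_asked = as.character(wet_asked),
    comment = as.character(comment),
    justification_code = as.character(justification_code)
  )
}

EVENT_COLS <- c(
  "proposed_time", "actual_time", "encouragement", "wet_asked",
  "comment", "justification_code"
)

as_event_tbl <- function(events) {
  events <- tibble::as_tibble(events)
  for (col in EVENT_COLS) {
    if (!col %in% names(events)) {
      events[[col]] <- if (grepl("time$", col)) NA_integer_ else NA_character_
    }
  }
  events$proposed_time <- as.integer(events$proposed_time)
  events$actual_time <- as.integer(events$actual_time)
  events$comment[is.na(events$comment)] <- ""
  events[EVENT_COLS]
}

#' Validate clinical-log invariants
#'
#' Errors if the log violates its contract: unknown arm/regime, an event
#' carrying neither a proposed nor an actual time, proposed times not
#' strictly increasing, or `wet_asked = "not_applicable"` used outside
#' bladder training.
#'
#' @param log A `clinical_log`.
#' @return The log, invisibly.
#' @export
validate_clinical_log <- function(log) {
  stopifnot(inherits(log, "clinical_log"))
  if (!log$arm %in% ARMS) {
    stop("unknown trial arm: ", log$arm)
  }
  if (!log$regime %in% REGIMES) {
    stop("unknown regime: ", log$regime)
  }
  ev <- log$events
  if (nrow(ev) > 0) {
    if (any(is.na(ev$proposed_time) & is.na(ev$actual_time))) {
      stop("log ", log$log_id,
           ": every event needs a proposed or an actual time")
    }
    prop <- ev$proposed_time[!is.na(ev$proposed_time)]
    if (length(prop) > 1 && any(diff(prop) <= 0)) {
      stop("log ", log$log_id,
           ": proposed voiding times must be strictly increasing")
    }
    wa <- ev$wet_asked[!is.na(ev$wet_asked)]
    na_ok <- log$regime == "bladder_training"
    if (!na_ok && any(wa == "not_applicable")) {
      stop("log ", log$log_id,
           ": wet_asked = not_applicable is reserved for bladder training")
    }
    if (na_ok && any(wa %in% ANSWERS)) {
      stop("log ", log$log_id,
           ": wet_asked is not applicable on bladder-training logs")
    }
    bad_ans <- setdiff(ev$encouragement[!is.na(ev$encouragement)], ANSWERS)
    if (length(bad_ans) > 0) {
      stop("log ", log$log_id, ": invalid encouragement answer: ",
           paste(bad_ans, collapse = ", "))
    }
  }
  invisible(log)
}

#' @export
print.clinical_log <- function(x, ...) {
  cat(sprintf(
    "<clinical_log %s> patient %s, site %s (%s), %s, %s\n",
    x$log_id, x$patient_id, x$site_id, x$arm, format(x$date), x$regime
  ))
  cat(sprintf(
    "  interval: %s [%s]  events: %d (%d proposed, %d actual)\n",
    if (nzchar(x$interval$raw_text)) x$interval$raw_text else "<blank>",
    x$interval$status, nrow(x$events),
    sum(!is.na(x$events$proposed_time)), sum(!is.na(x$events$actual_time))
  ))
  invisible(x)
}

proposed_times <- function(log) {
  log$events$proposed_time[!is.na(log$events$proposed_time)]
}

actual_times <- function(log) {
  sort(log$events$actual_time[!is.na(log$events$actual_time)])
}

#' Log-level metadata as a tibble
#'
#' Flattens a list of clinical logs to one row per log: identifiers, arm,
#' regime, date, parsed interval status/value and event counts. This is the
#' usual companion to [assess_fleet()] output when pooling results.
#'
#' @param logs List of `clinical_log` objects.
#' @return A tibble with one row per log.
#' @export
logs_tbl <- function(logs) {
  purrr::map_dfr(logs, function(log) {
    tibble::tibble(
      log_id = log$log_id,
      patient_id = log$patient_id,
      site_id = log$site_id,
      arm = log$arm,
      date = log$date,
      regime = log$regime,
      interval_text = log$interval$raw_text,
      interval_status = log$interval$status,
      interval_minutes = log$interval$value_minutes,
      n_events = nrow(log$events),
      n_proposed = sum(!is.na(log$events$proposed_time)),
      n_actual = sum(!is.na(log$events$actual_time))
    )
  })
}
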