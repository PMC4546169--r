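LOG_CSV_COLS <- c(
  "log_id", "patient_id", "site_id", "arm", "date", "regime",
  "interval_text", "proposed_time", "actual_time", "encouragement",
  "wet_asked", "comment", "justification_code"
)

#' Read clinical logs from CSV
#'
#' The on-disk format is UTF-8 CSV with one row per voiding event and
#' columns `log_id, patient_id, site_id, arm, date, regime, interval_text,
#' proposed_time, actual_time, encouragement, wet_asked, comment,
#' justification_code`. Log-level fields are repeated on each of a log's
#' rows; a blank cell means missing. A row with no event content at all is a
#' placeholder for a log that has no documented events.
#'
#' Reading degrades gracefully: a malformed time such as `"25:99"` becomes an
#' absent time and a warning in the load report; only structurally missing
#' columns are an error. The load report is attached to the result as
#' attribute `"load_report"` (see [load_report()]) and optionally written as
#' JSON.
#'
#' @param path CSV file path.
#' @param report_path Optional path for a companion JSON load report.
#' @return List of [clinical_log()] objects, with attribute `load_report`.
#' @export
read_logs <- function(path, report_path = NULL) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(LOG_CSV_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical-log CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  warnings <- list()
  note <- function(row, field, value, message) {
    warnings[[length(warnings) + 1]] <<- list(
      row = row, field = field, value = value, message = message
    )
  }

  blank_to_na <- function(x) ifelse(!is.na(x) & nzchar(trimws(x)), trimws(x), NA_character_)
  parse_time_col <- function(raw, field, rows) {
    raw <- blank_to_na(raw)
    out <- parse_time_of_day(raw)
    bad <- which(!is.na(raw) & is.na(out))
    for (i in bad) {
      note(rows[i], field, raw[i],
           sprintf("malformed time '%s'; recorded as absent", raw[i]))
    }
    out
  }

  logs <- list()
  if (nrow(df) > 0) {
    df$.row <- seq_len(nrow(df)) + 1L # physical line number incl. header
    for (id in unique(df$log_id)) {
      rows <- df[df$log_id == id, ]
      first <- rows[1, ]
      for (col in c("patient_id", "site_id", "arm", "date", "regime", "interval_text")) {
        vals <- unique(rows[[col]])
        if (length(vals) > 1) {
          note(first$.row, col, paste(vals, collapse = "|"),
               sprintf("inconsistent %s within log '%s'; first value used", col, id))
        }
      }
      ev <- tibble::tibble(
        proposed_time = parse_time_col(rows$proposed_time, "proposed_time", rows$.row),
        actual_time = parse_time_col(rows$actual_time, "actual_time", rows$.row),
        encouragement = blank_to_na(rows$encouragement),
        wet_asked = blank_to_na(rows$wet_asked),
        comment = dplyr::coalesce(blank_to_na(rows$comment), ""),
        justification_code = blank_to_na(rows$justification_code)
      )
      placeholder <- is.na(ev$proposed_time) & is.na(ev$actual_time) &
        is.na(ev$encouragement) &
        (is.na(ev$wet_asked) | ev$wet_asked == "not_applicable") &
        ev$comment == "" & is.na(ev$justification_code)
      ev <- ev[!placeholder, , drop = FALSE]

      log <- clinical_log(
        log_id = id,
        patient_id = dplyr::coalesce(blank_to_na(first$patient_id), ""),
        site_id = dplyr::coalesce(blank_to_na(first$site_id), ""),
        arm = dplyr::coalesce(blank_to_na(first$arm), ""),
        date = tryCatch(as.Date(first$date), error = function(e) {
          note(first$.row, "date", first$date, "unparseable date")
          as.Date(NA)
        }),
        regime = dplyr::coalesce(blank_to_na(first$regime), ""),
        interval_text = dplyr::coalesce(blank_to_na(first$interval_text), ""),
        events = ev,
        validate = FALSE
      )
      check <- tryCatch({
        validate_clinical_log(log)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(check)) {
        note(first$.row, "log", id, check)
      }
      logs[[length(logs) + 1]] <- log
    }
  }

  report <- list(
    path = as.character(path),
    n_rows = nrow(df),
    n_logs = length(logs),
    warnings = warnings
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  attr(logs, "load_report") <- report
  logs
}

#' @rdname read_logs
#' @param logs A list of clinical logs returned by [read_logs()].
#' @export
load_report <- function(logs) {
  attr(logs, "load_report")
}

#' Write clinical logs to CSV
#'
#' Inverse of [read_logs()]: `read_logs(write_logs(logs, path))` reproduces
#' every field, including the distinction between a missing answer and a
#' documented `"no"`. A log without events is written as a single
#' placeholder row so the log itself survives the round trip.
#'
#' @param logs List of [clinical_log()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_logs <- function(logs, path) {
  rows <- purrr::map_dfr(logs, function(log) {
    ev <- log$events
    if (nrow(ev) == 0) ev <- as_event_tbl(tibble::tibble(.rows = 1))
    tibble::tibble(
      log_id = log$log_id,
      patient_id = log$patient_id,
      site_id = log$site_id,
      arm = log$arm,
      date = format(log$date, "%Y-%m-%d"),
      regime = log$regime,
      interval_text = log$interval$raw_text,
      proposed_time = format_time_of_day(ev$proposed_time),
      actual_time = format_time_of_day(ev$actual_time),
      encouragement = ev$encouragement,
      wet_asked = ev$wet_asked,
      comment = ifelse(ev$comment == "", NA_character_, ev$comment),
      justification_code = ev$justification_code
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble::as_tibble(
      stats::setNames(rep(list(character()), length(LOG_CSV_COLS)), LOG_CSV_COLS)
    )
  }
  readr::write_csv(rows, path, na = "")
  invisible(path)
}
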