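#' Parse voiding-interval text
#'
#' The voiding interval written at the top of a clinical log prescribes the
#' fixed time between voids for that patient-day, e.g. `"2-hourly"` = 120
#' minutes. Valid documentation is a single number; a range such as
#' `"2 - 3 hourly"` does not define a schedule and fails the Stage-1 quality
#' indicator. This parser is total: every input maps to exactly one status,
#' never an error.
#'
#' The accepted grammar is a number (integer or half, e.g. `2.5`) followed by
#' a separator (hyphen, en-dash or space) and the word `hourly`
#' (case-insensitive). Two distinct numbers before `hourly` classify as
#' `range`. Blank or absent text is `missing`; anything else `unparseable`.
#'
#' @param raw_text Character vector of interval text as written on the log.
#' @return A tibble with one row per input and columns `raw_text`, `status`
#'   (one of `"single"`, `"range"`, `"missing"`, `"unparseable"`) and
#'   `value_minutes` (integer, populated only when `status == "single"`).
#' @examples
#' parse_interval(c("2-hourly", "2 - 3 hourly", "2.5 hourly", "", "soon"))
#' @export
parse_interval <- function(raw_text) {
  raw_text <- as.character(raw_text)
  n <- length(raw_text)
  status <- character(n)
  value <- rep(NA_integer_, n)

  num <- "[0-9]+(?:\\.5)?"
  sep <- "[-– ]"
  single_re <- paste0("^\\s*(", num, ")\\s*", sep, "\\s*hourly\\s*$")
  range_re <- paste0(
    "^\\s*(", num, ")\\s*", sep, "\\s*(", num, ")\\s*", sep, "?\\s*hourly\\s*$"
  )

  for (i in seq_len(n)) {
    txt <- raw_text[i]
    if (is.na(txt) || !nzchar(trimws(txt))) {
      status[i] <- "missing"
    } else if (grepl(range_re, txt, ignore.case = TRUE, perl = TRUE)) {
      m <- regmatches(txt, regexec(range_re, txt, ignore.case = TRUE, perl = TRUE))[[1]]
      status[i] <- if (m[2] == m[3]) "single" else "range"
      if (status[i] == "single") value[i] <- as.integer(round(as.numeric(m[2]) * 60))
    } else if (grepl(single_re, txt, ignore.case = TRUE, perl = TRUE)) {
      m <- regmatches(txt, regexec(single_re, txt, ignore.case = TRUE, perl = TRUE))[[1]]
      v <- as.numeric(m[2]) * 60
      if (v > 0) {
        status[i] <- "single"
        value[i] <- as.integer(round(v))
      } else {
        status[i] <- "unparseable"
      }
    } else {
      status[i] <- "unparseable"
    }
  }

  tibble::tibble(
    raw_text = ifelse(is.na(raw_text), "", raw_text),
    status = status,
    value_minutes = value
  )
}

#' Format a single-valued interval back to log text
#'
#' Inverse of [parse_interval()] for `single` intervals; used by the
#' simulator when writing synthetic logs.
#'
#' @param minutes Integer vector of interval lengths in minutes (multiples
#'   of 30).
#' @return Character such as `"2-hourly"` or `"2.5-hourly"`.
#' @export
format_interval <- function(minutes) {
  hours <- minutes / 60
  txt <- ifelse(hours == round(hours),
    sprintf("%d-hourly", as.integer(hours)),
    sprintf("%.1f-hourly", hours)
  )
  txt[is.na(minutes)] <- NA_character_
  txt
}
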