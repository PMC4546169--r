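#' Day window of the systematic voiding programme
#'
#' The SVP runs from 07:30 until 21:30; all proposed voiding times fall in
#' this window. Times are represented throughout the package as integer
#' minutes since midnight, so the window is \[450, 1290\].
#'
#' @format Integer scalars, minutes since midnight.
#' @name day-window
NULL

#' @rdname day-window
#' @export
DAY_START <- 450L

#' @rdname day-window
#' @export
DAY_END <- 1290L

#' Parse and format clock times
#'
#' Clock times are stored as integer minutes since midnight (0--1439).
#' `parse_time_of_day()` reads 24-hour `"HH:MM"` text; anything that does not
#' parse to a valid time of day yields `NA` (callers decide whether that is a
#' warning or an error). `format_time_of_day()` is its exact inverse.
#'
#' @param x Character vector of `"HH:MM"` strings (for `parse_time_of_day`)
#'   or integer minutes since midnight (for `format_time_of_day`).
#' @return Integer minutes since midnight, or `"HH:MM"` character; `NA`
#'   elements propagate.
#' @examples
#' parse_time_of_day("07:30")
#' format_time_of_day(1290L)
#' @export
parse_time_of_day <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^\\s*([01]?[0-9]|2[0-3]):[0-5][0-9]\\s*$", x)
  if (any(ok)) {
    parts <- strsplit(trimws(x[ok]), ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      as.integer(p[1]) * 60L + as.integer(p[2])
    }, integer(1))
  }
  out
}

#' @rdname parse_time_of_day
#' @export
format_time_of_day <- function(x) {
  x <- as.integer(x)
  bad <- !is.na(x) & (x < 0L | x > 1439L)
  if (any(bad)) {
    stop("time of day out of range [0, 1439]: ", paste(x[bad], collapse = ", "))
  }
  ifelse(is.na(x), NA_character_, sprintf("%02d:%02d", x %/% 60L, x %% 60L))
}
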