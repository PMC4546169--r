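PERIOD_DAYS <- 14L

#' Split a site's recruitment window into sampling strata
#'
#' The planned recruitment period is split into three near-equal contiguous
#' strata (any remainder days go to the last planned stratum). Sites that
#' extended recruitment get additional strata covering the extension, each at
#' most one planned-stratum long, so longer extensions contribute more
#' sampled periods.
#'
#' @param recruitment_start First day of recruitment.
#' @param planned_end Last day of the planned recruitment period.
#' @param actual_end Last day of recruitment (equal to `planned_end` when
#'   there was no extension).
#' @return Tibble with one row per stratum: `stratum`, `start`, `end`,
#'   `days`, `planned` (logical).
#' @export
build_strata <- function(recruitment_start, planned_end,
                         actual_end = planned_end) {
  recruitment_start <- as.Date(recruitment_start)
  planned_end <- as.Date(planned_end)
  actual_end <- as.Date(actual_end)
  if (!(recruitment_start < planned_end && planned_end <= actual_end)) {
    stop("need recruitment_start < planned_end <= actual_end")
  }

  planned_days <- as.integer(planned_end - recruitment_start) + 1L
  base <- planned_days %/% 3L
  lens <- c(base, base, planned_days - 2L * base)

  ext_days <- as.integer(actual_end - planned_end)
  while (ext_days > 0L) {
    take <- min(ext_days, base)
    lens <- c(lens, take)
    ext_days <- ext_days - take
  }

  ends <- recruitment_start + cumsum(lens) - 1L
  starts <- c(recruitment_start, utils::head(ends, -1) + 1L)
  strata <- tibble::tibble(
    stratum = seq_along(lens),
    start = starts,
    end = ends,
    days = as.integer(lens),
    planned = seq_along(lens) <= 3L
  )
  short <- strata$stratum[strata$days < PERIOD_DAYS]
  if (length(short) > 0) {
    stop("stratum ", paste(short, collapse = ", "), " is shorter than ",
         PERIOD_DAYS, " days; cannot host a sampling period")
  }
  strata
}

#' Draw two 14-day audit periods per stratum
#'
#' Within each stratum, one pair of non-overlapping 14-day periods is drawn
#' uniformly at random among all valid non-overlapping pairs of start days.
#' The draw is reproducible for a fixed seed and leaves the caller's RNG
#' state untouched. Three planned strata yield six periods; extension strata
#' add two periods each. The trial's site samples held between six and nine
#' periods, so a plan outside that range is flagged (`within_observed_range
#' = FALSE`), not rejected.
#'
#' @param strata Output of [build_strata()].
#' @param seed Integer seed.
#' @param site_id Optional site label carried into the plan.
#' @return A `sampling_plan`: list with `site_id`, `strata`, `periods`
#'   (tibble: `stratum`, `start`, `end`) and `within_observed_range`.
#' @export
sample_periods <- function(strata, seed, site_id = NA_character_) {
  infeasible <- strata$stratum[strata$days < 2L * PERIOD_DAYS]
  if (length(infeasible) > 0) {
    stop("stratum ", paste(infeasible, collapse = ", "),
         " cannot host two non-overlapping ", PERIOD_DAYS, "-day periods")
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  periods <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    # uniform draw over pairs (s1, s2) of start offsets with s2 - s1 >= 14,
    # indexed arithmetically: for each s1 there are (max_offset - s1 - 13)
    # admissible partners
    max_offset <- st$days - PERIOD_DAYS
    counts <- pmax(max_offset - 0:max_offset - (PERIOD_DAYS - 1L), 0L)
    r <- sample.int(sum(counts), 1L)
    s1 <- findInterval(r - 1L, cumsum(c(0L, counts)), left.open = FALSE) - 1L
    s2 <- s1 + PERIOD_DAYS + (r - 1L - sum(counts[seq_len(s1)]))
    starts <- st$start + c(s1, s2)
    tibble::tibble(
      stratum = st$stratum,
      start = starts,
      end = starts + PERIOD_DAYS - 1L
    )
  })

  structure(
    list(
      site_id = site_id,
      strata = strata,
      periods = periods,
      within_observed_range = nrow(periods) >= 6L && nrow(periods) <= 9L
    ),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf(
    "<sampling_plan%s> %d strata, %d periods of %d days%s\n",
    if (is.na(x$site_id)) "" else paste0(" ", x$site_id),
    nrow(x$strata), nrow(x$periods), PERIOD_DAYS,
    if (x$within_observed_range) "" else " (outside the observed 6-9 range)"
  ))
  print(x$periods)
  invisible(x)
}

#' Serialise / restore a sampling plan
#'
#' @param plan A `sampling_plan`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_sampling_plan()` returns the plan.
#' @export
write_sampling_plan <- function(plan, path) {
  jsonlite::write_json(
    list(
      site_id = plan$site_id,
      strata = dplyr::mutate(plan$strata, dplyr::across(c("start", "end"), as.character)),
      periods = dplyr::mutate(plan$periods, dplyr::across(c("start", "end"), as.character)),
      within_observed_range = plan$within_observed_range
    ),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' @rdname write_sampling_plan
#' @export
read_sampling_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(df) {
    df <- tibble::as_tibble(df)
    df$start <- as.Date(df$start)
    df$end <- as.Date(df$end)
    df
  }
  structure(
    list(
      site_id = if (is.null(raw$site_id)) NA_character_ else raw$site_id,
      strata = fix(raw$strata),
      periods = fix(raw$periods),
      within_observed_range = raw$within_observed_range
    ),
    class = "sampling_plan"
  )
}

#' Select the clinical logs covered by a sampling plan
#'
#' The audit sample comprises all logs for all patients on the programme
#' whose date falls inside any of the plan's 14-day periods. Order is
#' preserved and, because periods are disjoint, no log is selected twice.
#'
#' @param logs List of [clinical_log()] objects.
#' @param plan A `sampling_plan`.
#' @return The selected sublist of `logs`.
#' @export
select_logs <- function(logs, plan) {
  keep <- vapply(logs, function(log) {
    isTRUE(any(log$date >= plan$periods$start & log$date <= plan$periods$end))
  }, logical(1))
  logs[keep]
}
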