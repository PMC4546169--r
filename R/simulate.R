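# The SVP's agreed leeway; the generator uses it to decide which occasions
# are candidates for a clinically justifiable comment.
SVP_LEEWAY <- 30L

#' Simulation configuration
#'
#' Parameters of the synthetic clinical-log generator. The defaults emulate
#' the documentation behaviour observed when the assessment method was
#' developed: intervals occasionally missing or written as a range, schedules
#' with missing entries or miscalculated gaps, voids that drift around their
#' proposed times or go undocumented, and best-practice answers that are
#' sometimes left blank rather than answered "no".
#'
#' @param n_sites_per_arm Sites per trial arm (both arms are generated).
#' @param n_patients_per_site Patients per site.
#' @param days_per_patient Consecutive SVP days (= logs) per patient.
#' @param p_prompted_voiding Probability a patient is on prompted voiding
#'   (vs bladder training).
#' @param interval_choices Named numeric vector: names are interval lengths
#'   in minutes, values their probabilities (summing to 1).
#' @param p_interval_missing,p_interval_range Probability the interval is
#'   left blank / written as a range such as "2 - 3 hourly".
#' @param p_schedule_gap Per interior schedule slot, probability its proposed
#'   time is left blank (first and last slots are never blanked, so the
#'   missing entry always sits between the documented endpoints).
#' @param p_schedule_miscalc Per log, probability the whole schedule is laid
#'   with every gap 60 minutes shorter than the documented interval —
#'   the classic "3-hourly interval, 2-hour gaps" miscalculation.
#' @param timing_sd_minutes SD of the Gaussian deviation of actual voiding
#'   times around their proposed times (rounded to the minute, clipped to
#'   the 07:30--21:30 day window).
#' @param p_void_missing Per slot, probability no actual void is documented.
#' @param p_exempt_comment Per missed or missing occasion (void absent or
#'   beyond the 30-minute leeway), probability a clinically justifiable
#'   comment with a justification code is recorded.
#' @param p_encourage_yes,p_encourage_missing Per occasion, probabilities of
#'   a "yes" / a blank answer to the encouragement question (remainder is
#'   "no").
#' @param p_wet_yes,p_wet_missing Same for the "asked if wet" question
#'   (prompted voiding only).
#' @param seed Integer seed; identical configs generate identical fleets.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites_per_arm = 4L,
                              n_patients_per_site = 10L,
                              days_per_patient = 10L,
                              p_prompted_voiding = 0.9,
                              interval_choices = c(
                                "120" = 0.50, "150" = 0.25, "180" = 0.25
                              ),
                              p_interval_missing = 0.10,
                              p_interval_range = 0.06,
                              p_schedule_gap = 0.08,
                              p_schedule_miscalc = 0.35,
                              timing_sd_minutes = 20,
                              p_void_missing = 0.40,
                              p_exempt_comment = 0.10,
                              p_encourage_yes = 0.58,
                              p_encourage_missing = 0.25,
                              p_wet_yes = 0.60,
                              p_wet_missing = 0.25,
                              seed = 1L) {
  config <- list(
    n_sites_per_arm = as.integer(n_sites_per_arm),
    n_patients_per_site = as.integer(n_patients_per_site),
    days_per_patient = as.integer(days_per_patient),
    p_prompted_voiding = p_prompted_voiding,
    interval_choices = interval_choices,
    p_interval_missing = p_interval_missing,
    p_interval_range = p_interval_range,
    p_schedule_gap = p_schedule_gap,
    p_schedule_miscalc = p_schedule_miscalc,
    timing_sd_minutes = timing_sd_minutes,
    p_void_missing = p_void_missing,
    p_exempt_comment = p_exempt_comment,
    p_encourage_yes = p_encourage_yes,
    p_encourage_missing = p_encourage_missing,
    p_wet_yes = p_wet_yes,
    p_wet_missing = p_wet_missing,
    seed = as.integer(seed)
  )
  validate_simulation_config(config)
  structure(config, class = "simulation_config")
}

validate_simulation_config <- function(config) {
  probs <- c(
    "p_prompted_voiding", "p_interval_missing", "p_interval_range",
    "p_schedule_gap", "p_schedule_miscalc", "p_void_missing",
    "p_exempt_comment", "p_encourage_yes", "p_encourage_missing",
    "p_wet_yes", "p_wet_missing"
  )
  for (p in probs) {
    if (!is.numeric(config[[p]]) || config[[p]] < 0 || config[[p]] > 1) {
      stop("config error: ", p, " must be a probability in [0, 1]")
    }
  }
  if (config$p_interval_missing + config$p_interval_range > 1) {
    stop("config error: p_interval_missing + p_interval_range must be <= 1")
  }
  if (config$p_encourage_yes + config$p_encourage_missing > 1) {
    stop("config error: p_encourage_yes + p_encourage_missing must be <= 1")
  }
  if (config$p_wet_yes + config$p_wet_missing > 1) {
    stop("config error: p_wet_yes + p_wet_missing must be <= 1")
  }
  iv <- config$interval_choices
  if (is.null(names(iv)) || any(is.na(suppressWarnings(as.integer(names(iv)))))) {
    stop("config error: interval_choices must be named by interval minutes")
  }
  if (abs(sum(iv) - 1) > 1e-8 || any(iv < 0)) {
    stop("config error: interval_choices probabilities must be >= 0 and sum to 1")
  }
  if (any(as.integer(names(iv)) > DAY_END - DAY_START)) {
    stop("config error: interval longer than the SVP day window")
  }
  if (config$timing_sd_minutes < 0) {
    stop("config error: timing_sd_minutes must be nonnegative")
  }
  if (any(c(config$n_sites_per_arm, config$n_patients_per_site,
            config$days_per_patient) < 1)) {
    stop("config error: fleet dimensions must be positive")
  }
  invisible(config)
}

#' Read a simulation config from YAML
#'
#' Keys mirror the arguments of [simulation_config()]; omitted keys keep
#' their defaults. `interval_choices` is a mapping from interval minutes to
#' probability.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$interval_choices)) {
    vals$interval_choices <- unlist(vals$interval_choices)
  }
  unknown <- setdiff(names(vals), names(formals(simulation_config)))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, vals)
}

draw_answer <- function(n, p_yes, p_missing) {
  u <- stats::runif(n)
  ifelse(u < p_yes, "yes", ifelse(u < p_yes + p_missing, NA_character_, "no"))
}

#' Generate a synthetic fleet of clinical logs
#'
#' Produces one log per patient-day across both trial arms, with the error
#' processes configured in [simulation_config()]. Every log is generated the
#' same way:
#'
#' 1. an interval is drawn from `interval_choices`; its documentation is
#'    blank with `p_interval_missing`, a range (e.g. "2 - 3 hourly") with
#'    `p_interval_range`, else the single value;
#' 2. a schedule is laid from 07:30 at that interval up to 21:30; with
#'    `p_schedule_miscalc` every gap is shrunk by 60 minutes (where that
#'    leaves a positive gap), and each interior slot's proposed time is then
#'    blanked with `p_schedule_gap`;
#' 3. each slot's actual void is documented with `1 - p_void_missing`, at
#'    the proposed time plus Gaussian noise (`timing_sd_minutes`), rounded
#'    to the minute and clipped to the day window;
#' 4. occasions missing a void or outside the 30-minute leeway get a
#'    justification code with `p_exempt_comment`; best-practice answers are
#'    drawn per occasion.
#'
#' Identical configs (including `seed`) generate identical fleets; the
#' caller's RNG state is untouched.
#'
#' @param config A [simulation_config()].
#' @param start_date First SVP day for every patient.
#' @return List of [clinical_log()] objects.
#' @export
generate_fleet <- function(config, start_date = as.Date("2011-03-01")) {
  validate_simulation_config(config)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  intervals <- as.integer(names(config$interval_choices))
  logs <- list()
  k <- 0L

  for (arm in ARMS) {
    arm_tag <- if (arm == "intervention") "INT" else "SUP"
    for (s in seq_len(config$n_sites_per_arm)) {
      site_id <- sprintf("%s%02d", arm_tag, s)
      for (p in seq_len(config$n_patients_per_site)) {
        patient_id <- sprintf("%s-P%03d", site_id, p)
        regime <- if (stats::runif(1) < config$p_prompted_voiding) {
          "prompted_voiding"
        } else {
          "bladder_training"
        }
        for (d in seq_len(config$days_per_patient)) {
          k <- k + 1L
          logs[[k]] <- simulate_log(
            config, intervals,
            log_id = sprintf("L%05d", k),
            patient_id = patient_id, site_id = site_id, arm = arm,
            date = start_date + (d - 1L), regime = regime
          )
        }
      }
    }
  }
  logs
}

simulate_log <- function(config, intervals, log_id, patient_id, site_id,
                         arm, date, regime) {
  interval <- if (length(intervals) == 1) {
    intervals
  } else {
    sample(intervals, 1L, prob = config$interval_choices)
  }

  u <- stats::runif(1)
  interval_text <- if (u < config$p_interval_missing) {
    ""
  } else if (u < config$p_interval_missing + config$p_interval_range) {
    sprintf("%s – %s hourly", fmt_hours(interval), fmt_hours(interval + 60L))
  } else {
    format_interval(interval)
  }

  gap <- interval
  if (stats::runif(1) < config$p_schedule_miscalc && interval - 60L > 0L) {
    gap <- interval - 60L
  }
  slots <- seq(DAY_START, DAY_END, by = gap)
  n <- length(slots)

  proposed <- as.integer(slots)
  if (n > 2 && config$p_schedule_gap > 0) {
    blank <- c(FALSE, stats::runif(n - 2) < config$p_schedule_gap, FALSE)
    proposed[blank] <- NA_integer_
  }

  actual <- rep(NA_integer_, n)
  voided <- stats::runif(n) >= config$p_void_missing
  if (any(voided)) {
    dev <- round(stats::rnorm(sum(voided), 0, config$timing_sd_minutes))
    actual[voided] <- pmin(pmax(slots[voided] + as.integer(dev), DAY_START), DAY_END)
  }

  missed <- !voided | abs(actual - slots) > SVP_LEEWAY
  missed[is.na(missed)] <- TRUE
  exempt <- missed & stats::runif(n) < config$p_exempt_comment
  code <- rep(NA_character_, n)
  comment <- rep("", n)
  if (any(exempt)) {
    code[exempt] <- sample(DEFAULT_EXEMPTION_CODES, sum(exempt), replace = TRUE)
    comment[exempt] <- "clinically justifiable; see code"
  }

  encouragement <- draw_answer(n, config$p_encourage_yes, config$p_encourage_missing)
  wet_asked <- if (regime == "prompted_voiding") {
    draw_answer(n, config$p_wet_yes, config$p_wet_missing)
  } else {
    rep("not_applicable", n)
  }

  ev <- tibble::tibble(
    proposed_time = proposed,
    actual_time = actual,
    encouragement = encouragement,
    wet_asked = wet_asked,
    comment = comment,
    justification_code = code
  )
  ev <- ev[!(is.na(ev$proposed_time) & is.na(ev$actual_time)), , drop = FALSE]

  clinical_log(
    log_id = log_id, patient_id = patient_id, site_id = site_id, arm = arm,
    date = date, regime = regime, interval_text = interval_text, events = ev,
    validate = FALSE
  )
}

fmt_hours <- function(minutes) {
  h <- minutes / 60
  if (h == round(h)) sprintf("%d", as.integer(h)) else sprintf("%.1f", h)
}

#' Analytic expectations for a simulated fleet
#'
#' Closed-form expectations of the pipeline's summary statistics under the
#' generator's model, used as the oracle in parameter-recovery tests.
#' Stage-3 quantities are on the pooled-occasion basis (total met / total
#' assessed across the fleet) and account for the clipping of actual voiding
#' times to the day window: a slot proposed at the window boundary can only
#' deviate inwards, so its hit probability is \eqn{\Phi(w/\sigma)} rather
#' than \eqn{2\Phi(w/\sigma) - 1}.
#'
#' @param config A [simulation_config()].
#' @return Named list of expectations: `stage1_pass`,
#'   `stage2_pass_given_stage1`, `stage2_pass` (overall),
#'   `stage3_slot_within_window` (timing only, given a documented void),
#'   `stage3_hit_rate` (pooled, with missing voids and exemptions),
#'   `stage4a_yes_rate`, `stage4b_yes_rate`, `pct_prompted_voiding`,
#'   `mean_interval_hours` and `mean_n_proposed` (both among
#'   Stage-1-and-2 passers).
#' @export
expected_summaries <- function(config) {
  validate_simulation_config(config)
  intervals <- as.integer(names(config$interval_choices))
  q <- as.numeric(config$interval_choices)

  n_slots <- vapply(intervals, function(i) length(seq(DAY_START, DAY_END, by = i)), integer(1))
  # miscalculation only bites where shrinking the gap leaves it positive
  p_pass2 <- (1 - config$p_schedule_miscalc * (intervals > 60L)) *
    (1 - config$p_schedule_gap)^pmax(n_slots - 2L, 0L)

  stage1 <- 1 - config$p_interval_missing - config$p_interval_range
  stage2_given1 <- sum(q * p_pass2)

  # interval mix among Stage-1-and-2 passers
  w <- q * p_pass2
  w <- w / sum(w)

  met <- 0
  assessed <- 0
  hit_num <- 0
  slot_total <- 0
  for (j in seq_along(intervals)) {
    slots <- seq(DAY_START, DAY_END, by = intervals[j])
    h <- vapply(slots, slot_hit_prob, numeric(1),
      sd = config$timing_sd_minutes, window = SVP_LEEWAY
    )
    m <- (1 - config$p_void_missing) * h
    a <- 1 - (1 - m) * config$p_exempt_comment
    met <- met + w[j] * sum(m)
    assessed <- assessed + w[j] * sum(a)
    hit_num <- hit_num + w[j] * sum(h)
    slot_total <- slot_total + w[j] * length(slots)
  }

  list(
    stage1_pass = stage1,
    stage2_pass_given_stage1 = stage2_given1,
    stage2_pass = stage1 * stage2_given1,
    stage3_slot_within_window = hit_num / slot_total,
    stage3_hit_rate = met / assessed,
    stage4a_yes_rate = config$p_encourage_yes,
    stage4b_yes_rate = config$p_wet_yes,
    pct_prompted_voiding = 100 * config$p_prompted_voiding,
    mean_interval_hours = sum(w * intervals) / 60,
    mean_n_proposed = sum(w * n_slots)
  )
}

# P(|clip(p + Z) - p| <= window) for Z ~ N(0, sd^2), clipping to the day
# window. A deviation past a boundary within `window` of p clips back to the
# boundary and still counts as a hit.
slot_hit_prob <- function(p, sd, window, day_start = DAY_START, day_end = DAY_END) {
  if (sd == 0) {
    return(1)
  }
  lower <- if (p - day_start <= window) 0 else stats::pnorm(-window / sd)
  upper <- if (day_end - p <= window) 1 else stats::pnorm(window / sd)
  upper - lower
}
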