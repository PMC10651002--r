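#' Cohort tables: I/O, validation, and eligibility
#'
#' A cohort is a tibble with one row per pregnancy. Mandatory columns:
#' `woman_id`, `enrollment_date`, `us_ga_weeks`, `us_date`, `lmp_date`,
#' `fundal_height_cm`, `recall_months`, `self_visits_enroll`,
#' `delivery_date`, `outcome`, `ltfu`, `ltfu_date`. Baseline covariates
#' (`age_years`, `district`, `literate`, `wealth_q`, `ethnicity`,
#' `primiparous`, `hist_stillbirth`, `hist_preterm`, `walk_minutes`) and
#' any unrecognised columns ride along unchanged. Dates are ISO-8601 in
#' files; one cohort-wide format, no per-row sniffing.
#'
#' Visits are a tibble with columns `woman_id`, `visit_date`, `source`
#' (`chart_prospective`, `chart_retrospective`, or `self_report`); chart
#' sources must be dated.
#'
#' @name cohort-data
NULL

COHORT_MANDATORY <- c(
  "woman_id", "enrollment_date", "us_ga_weeks", "us_date", "lmp_date",
  "fundal_height_cm", "recall_months", "self_visits_enroll",
  "delivery_date", "outcome", "ltfu", "ltfu_date"
)

COHORT_COVARIATES <- c(
  "age_years", "district", "literate", "wealth_q", "ethnicity",
  "primiparous", "hist_stillbirth", "hist_preterm", "walk_minutes"
)

OUTCOME_LEVELS <- c("live_birth", "stillbirth", "miscarriage", "unknown")
VISIT_SOURCES <- c("chart_prospective", "chart_retrospective", "self_report")

cohort_col_types <- function() {
  readr::cols(
    woman_id = readr::col_character(),
    enrollment_date = readr::col_date("%Y-%m-%d"),
    us_ga_weeks = readr::col_double(),
    us_date = readr::col_date("%Y-%m-%d"),
    lmp_date = readr::col_date("%Y-%m-%d"),
    fundal_height_cm = readr::col_double(),
    recall_months = readr::col_integer(),
    self_visits_enroll = readr::col_integer(),
    delivery_date = readr::col_date("%Y-%m-%d"),
    outcome = readr::col_character(),
    ltfu = readr::col_logical(),
    ltfu_date = readr::col_date("%Y-%m-%d"),
    age_years = readr::col_double(),
    district = readr::col_character(),
    literate = readr::col_logical(),
    wealth_q = readr::col_integer(),
    ethnicity = readr::col_character(),
    primiparous = readr::col_logical(),
    hist_stillbirth = readr::col_logical(),
    hist_preterm = readr::col_logical(),
    walk_minutes = readr::col_double(),
    .default = readr::col_character()
  )
}

#' Read and validate a cohort table
#'
#' @param path Path to a UTF-8, comma-delimited cohort file with a header
#'   row matching the data dictionary (see [cohort-data]).
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_anccov(paste0("cohort file not found: ", path), "anccov_io")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(COHORT_MANDATORY, header)
  if (length(missing) > 0) {
    stop_anccov(paste0("cohort file is missing mandatory column(s): ",
                       paste(missing, collapse = ", ")),
                "anccov_schema")
  }
  cohort <- readr::read_csv(path, col_types = cohort_col_types(),
                            na = c("", "NA"), show_col_types = FALSE)
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    first <- probs[1, ]
    stop_anccov(sprintf(
      "unparseable value in row %d, column %d (expected %s, got '%s')",
      first$row, first$col, first$expected, first$actual),
      "anccov_parse")
  }
  validate_cohort(cohort)
}

#' Write a cohort table
#'
#' Lossless inverse of [read_cohort()]: dates as ISO-8601, UTF-8,
#' comma-delimited.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read and validate a visits table
#'
#' @param path Path to a comma-delimited visits file with columns
#'   `woman_id`, `visit_date`, `source`.
#' @return A validated visits tibble.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) {
    stop_anccov(paste0("visits file not found: ", path), "anccov_io")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(c("woman_id", "visit_date", "source"), header)
  if (length(missing) > 0) {
    stop_anccov(paste0("visits file is missing mandatory column(s): ",
                       paste(missing, collapse = ", ")),
                "anccov_schema")
  }
  visits <- readr::read_csv(
    path,
    col_types = readr::cols(
      woman_id = readr::col_character(),
      visit_date = readr::col_date("%Y-%m-%d"),
      source = readr::col_character()
    ),
    na = c("", "NA"), show_col_types = FALSE)
  validate_visits(visits)
}

#' @rdname read_visits
#' @param visits A validated visits tibble.
#' @export
write_visits <- function(visits, path) {
  validate_visits(visits)
  readr::write_csv(visits, path, na = "")
  invisible(path)
}

#' Validate cohort / visits invariants
#'
#' Checks the row-level invariants: unique `woman_id`; loss to follow-up
#' mutually exclusive with a recorded delivery; non-negative self-reported
#' visit counts; known outcome labels; chart visits dated.
#'
#' @param cohort A cohort tibble.
#' @return The input, invisibly validated (errors on violation).
#' @export
validate_cohort <- function(cohort) {
  if (anyDuplicated(cohort$woman_id)) {
    dup <- cohort$woman_id[duplicated(cohort$woman_id)][1]
    stop_anccov(paste0("duplicate woman_id: ", dup), "anccov_invalid")
  }
  if (any(!is.na(cohort$self_visits_enroll) & cohort$self_visits_enroll < 0)) {
    stop_anccov("negative self-reported visit count", "anccov_invalid")
  }
  bad_outcome <- setdiff(unique(cohort$outcome[!is.na(cohort$outcome)]),
                         OUTCOME_LEVELS)
  if (length(bad_outcome) > 0) {
    stop_anccov(paste0("unknown outcome label(s): ",
                       paste(bad_outcome, collapse = ", ")),
                "anccov_invalid")
  }
  ltfu <- !is.na(cohort$ltfu) & cohort$ltfu
  if (any(ltfu & !is.na(cohort$delivery_date))) {
    stop_anccov("lost-to-follow-up record carries a delivery date",
                "anccov_invalid")
  }
  if (any(ltfu & is.na(cohort$ltfu_date))) {
    stop_anccov("lost-to-follow-up record has no censoring date",
                "anccov_invalid")
  }
  cohort
}

#' @rdname validate_cohort
#' @param visits A visits tibble.
#' @export
validate_visits <- function(visits) {
  bad_src <- setdiff(unique(visits$source), VISIT_SOURCES)
  if (length(bad_src) > 0) {
    stop_anccov(paste0("unknown visit source(s): ",
                       paste(bad_src, collapse = ", ")),
                "anccov_invalid")
  }
  chart <- visits$source %in% c("chart_prospective", "chart_retrospective")
  if (any(chart & is.na(visits$visit_date))) {
    stop_anccov("chart-sourced visit without a date", "anccov_invalid")
  }
  visits
}

#' Apply the eligibility exclusions
#'
#' Exclusions are applied in a fixed order so the tally buckets are
#' disjoint: (1) miscarriages (pregnancy losses before 28 weeks); (2)
#' implausible documented gestational ages — enrollment GA <=0 or >=46
#' weeks, delivery GA <28 or >=46 weeks, or GA unresolvable from the
#' dating evidence; (3) loss to follow-up. Lost women are returned
#' separately (not discarded) because the sensitivity scenarios need their
#' pre-censoring visit history.
#'
#' The returned cohorts are augmented with the resolved anchor columns
#' (`ga_ref_date`, `ga_ref_days`, `ga_method`) and derived
#' `ga_enroll_weeks` / `ga_delivery_weeks`.
#'
#' @param cohort A validated cohort tibble.
#' @param discrepancy_limit_days Passed to the GA dating hierarchy.
#' @return A list with `analysis` (eligible, followed-to-delivery cohort),
#'   `ltfu` (lost-to-follow-up cohort, eligible but censored), and `tally`
#'   (one-row tibble: `n_input`, `n_miscarriage`, `n_implausible_ga`,
#'   `n_ltfu`, `n_analysis`).
#' @export
apply_exclusions <- function(cohort, discrepancy_limit_days = 10) {
  cohort <- validate_cohort(cohort)
  aug <- augment_ga(cohort, discrepancy_limit_days)

  is_misc <- !is.na(aug$outcome) & aug$outcome == "miscarriage"
  pl <- plausibility_flags(aug$ga_enroll_weeks, aug$ga_delivery_weeks)
  is_implaus <- !is_misc & (is.na(aug$ga_method) | !pl$enroll_ok | !pl$delivery_ok)
  if (any(is.na(aug$ga_method) & !is_misc)) {
    rlang::warn(sprintf(
      "%d record(s) with unresolvable gestational age routed to the implausible-GA bucket",
      sum(is.na(aug$ga_method) & !is_misc)))
  }
  is_ltfu <- !is_misc & !is_implaus & !is.na(aug$ltfu) & aug$ltfu

  keep <- !is_misc & !is_implaus & !is_ltfu
  tally <- tibble::tibble(
    n_input = nrow(aug),
    n_miscarriage = sum(is_misc),
    n_implausible_ga = sum(is_implaus),
    n_ltfu = sum(is_ltfu),
    n_analysis = sum(keep)
  )
  list(analysis = aug[keep, , drop = FALSE],
       ltfu = aug[is_ltfu, , drop = FALSE],
       tally = tally)
}

# attach anchor + GA-at-landmark columns to a cohort
augment_ga <- function(cohort, discrepancy_limit_days = 10) {
  if (all(c("ga_ref_date", "ga_ref_days", "ga_method") %in% names(cohort))) {
    anch <- cohort[, c("woman_id", "ga_ref_date", "ga_ref_days", "ga_method")]
  } else {
    anch <- resolve_anchors(cohort, discrepancy_limit_days)
    cohort <- dplyr::left_join(cohort, anch, by = "woman_id")
  }
  cohort$ga_enroll_weeks <- (cohort$ga_ref_days +
    as.integer(cohort$enrollment_date - cohort$ga_ref_date)) / 7
  cohort$ga_delivery_weeks <- (cohort$ga_ref_days +
    as.integer(cohort$delivery_date - cohort$ga_ref_date)) / 7
  cohort
}

#' Select the early-enrollment subcohort
#'
#' Keeps women whose documented enrollment gestational age is strictly
#' below `ga_threshold_weeks` (default 13, the first-trimester cut used
#' for the primary coverage estimates, where visit counts are mostly
#' prospective).
#'
#' @param cohort A cohort tibble carrying `ga_enroll_weeks` (as produced
#'   by [apply_exclusions()]).
#' @param ga_threshold_weeks Threshold in weeks.
#' @param complement If `TRUE`, return the complement (enrolled at or
#'   after the threshold) instead.
#' @return The filtered cohort tibble.
#' @export
select_subcohort <- function(cohort, ga_threshold_weeks = 13,
                             complement = FALSE) {
  if (!"ga_enroll_weeks" %in% names(cohort)) {
    stop_anccov("cohort lacks resolved enrollment GA; run apply_exclusions() first",
                "anccov_invalid")
  }
  if (any(is.na(cohort$ga_enroll_weeks))) {
    stop_anccov("unresolved enrollment GA in cohort", "anccov_invalid")
  }
  early <- cohort$ga_enroll_weeks < ga_threshold_weeks
  cohort[if (complement) !early else early, , drop = FALSE]
}
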