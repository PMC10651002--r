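#' Gestational-age dating
#'
#' Each pregnancy is dated once, by the best available evidence, into a
#' gestational-age (GA) anchor: a reference date plus the GA in integer days
#' on that date. All downstream GA arithmetic (enrollment GA, delivery GA,
#' visit-window assignment) is day counting from the anchor, so week
#' boundaries such as "16 to <28 weeks" are exact integer comparisons with
#' no floating-point ambiguity.
#'
#' The evidence hierarchy, in order:
#' 1. ultrasound, when the scan itself was done before 16 weeks GA
#'    (`ultrasound_early`);
#' 2. last menstrual period (LMP), when a later (>=16-week) scan exists but
#'    the LMP-implied GA at the scan date disagrees with the scan by at most
#'    `discrepancy_limit_days` (`lmp_confirmed`);
#' 3. LMP alone when no ultrasound was done (`lmp`);
#' 4. fundal height, converted at 1 cm per week of gestation at the
#'    measurement date (`fundal_height`);
#' 5. maternal recall of months pregnant, at 365.25/12 days per month
#'    (`maternal_recall`).
#'
#' A >=16-week ultrasound whose LMP cross-check fails (or with no LMP at
#' all) falls through to fundal height or recall; if no branch applies the
#' record is unresolvable and an error of class `anccov_ga_unresolvable`
#' is raised (or, in vectorised use, the record is flagged).
#'
#' @name ga-dating
NULL

GA_METHODS <- c("ultrasound_early", "lmp_confirmed", "lmp",
                "fundal_height", "maternal_recall")

#' Resolve the best gestational-age anchor for one pregnancy
#'
#' @param evidence A list (or one-row data frame) with elements
#'   `ultrasound_ga_weeks`, `ultrasound_date`, `lmp_date`,
#'   `fundal_height_cm`, `maternal_recall_months`, each possibly `NA`,
#'   and `measurement_date` (the date fundal height / recall were taken,
#'   typically enrollment).
#' @param discrepancy_limit_days Maximum allowed disagreement, in days,
#'   between the LMP-implied GA and a >=16-week ultrasound GA at the scan
#'   date for the LMP to be accepted as confirmed. Default 10 days, a
#'   conventional second-trimester redating cut.
#' @param cm_per_week Fundal-height dating rule: centimetres of fundal
#'   height per week of gestation. Default 1.
#' @param days_per_month Days per month for maternal recall. Default
#'   365.25/12.
#' @return A list with `reference_date` (Date), `ga_at_reference_days`
#'   (non-negative integer), and `method` (one of
#'   `r paste(GA_METHODS, collapse = ", ")`).
#' @export
#' @examples
#' best_ga_anchor(list(
#'   ultrasound_ga_weeks = 10, ultrasound_date = as.Date("2019-03-01"),
#'   lmp_date = as.Date("2018-12-20"), fundal_height_cm = NA,
#'   maternal_recall_months = NA, measurement_date = as.Date("2019-03-01")))
best_ga_anchor <- function(evidence, discrepancy_limit_days = 10,
                           cm_per_week = 1,
                           days_per_month = DAYS_PER_MONTH) {
  us_ga  <- evidence$ultrasound_ga_weeks
  us_dt  <- evidence$ultrasound_date
  lmp    <- evidence$lmp_date
  fh     <- evidence$fundal_height_cm
  recall <- evidence$maternal_recall_months
  mdate  <- evidence$measurement_date

  has <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

  if (has(us_ga) && !has(us_dt)) {
    stop_anccov("ultrasound GA present without an ultrasound date",
                "anccov_ga_invalid_evidence")
  }

  anchor <- function(ref, days, method) {
    days <- as.integer(round(days))
    if (days < 0L) {
      stop_anccov("negative gestational age at anchor", "anccov_ga_domain")
    }
    list(reference_date = as.Date(ref), ga_at_reference_days = days,
         method = method)
  }

  # branch 1: early ultrasound
  if (has(us_ga) && us_ga < 16) {
    return(anchor(us_dt, us_ga * 7, "ultrasound_early"))
  }
  # branch 2: LMP cross-checked against a late ultrasound
  if (has(us_ga) && has(lmp)) {
    lmp_ga_at_scan <- as.integer(as.Date(us_dt) - as.Date(lmp))
    if (abs(lmp_ga_at_scan - us_ga * 7) <= discrepancy_limit_days) {
      return(anchor(lmp, 0, "lmp_confirmed"))
    }
    # discrepancy exceeded: LMP distrusted, fall through to 4/5
  } else if (has(lmp) && !has(us_ga)) {
    # branch 3: LMP alone
    return(anchor(lmp, 0, "lmp"))
  }
  # branch 4: fundal height at the measurement date
  if (has(fh)) {
    if (!has(mdate)) {
      stop_anccov("fundal height present without a measurement date",
                  "anccov_ga_invalid_evidence")
    }
    return(anchor(mdate, fh / cm_per_week * 7, "fundal_height"))
  }
  # branch 5: maternal recall in months
  if (has(recall)) {
    if (!has(mdate)) {
      stop_anccov("maternal recall present without a measurement date",
                  "anccov_ga_invalid_evidence")
    }
    return(anchor(mdate, recall * days_per_month, "maternal_recall"))
  }
  stop_anccov("gestational age unresolvable: no usable dating evidence",
              "anccov_ga_unresolvable")
}

#' Gestational age at a date under an anchor
#'
#' Affine day arithmetic: `(ga_at_reference_days + (date - reference_date)) / 7`
#' weeks. Exact on day counts; a negative result is a domain error.
#'
#' @param anchor A GA anchor as returned by [best_ga_anchor()].
#' @param date Date vector.
#' @return GA in (fractional) weeks, one per `date`.
#' @export
ga_at <- function(anchor, date) {
  days <- ga_days_at(anchor, date)
  days / 7
}

#' @rdname ga_at
#' @return `ga_days_at()` returns the GA in integer days.
#' @export
ga_days_at <- function(anchor, date) {
  days <- anchor$ga_at_reference_days +
    as.integer(as.Date(date) - anchor$reference_date)
  if (any(!is.na(days) & days < 0L)) {
    stop_anccov("date precedes conception under this anchor",
                "anccov_ga_domain")
  }
  days
}

#' Plausibility of documented gestational ages
#'
#' Enrollment GA is plausible iff strictly between 0 and 46 weeks
#' (excluded iff <=0 or >=46); delivery GA iff in [28, 46) weeks. An
#' absent delivery GA (loss to follow-up) is vacuously plausible.
#'
#' @param ga_enroll_weeks,ga_delivery_weeks Numeric vectors of GA in weeks
#'   (`NA` allowed for delivery).
#' @return A tibble with logical columns `enroll_ok` and `delivery_ok`.
#' @export
plausibility_flags <- function(ga_enroll_weeks, ga_delivery_weeks) {
  tibble::tibble(
    enroll_ok = !is.na(ga_enroll_weeks) &
      ga_enroll_weeks > 0 & ga_enroll_weeks < 46,
    delivery_ok = is.na(ga_delivery_weeks) |
      (ga_delivery_weeks >= 28 & ga_delivery_weeks < 46)
  )
}

# Resolve anchors for every row of a cohort table; unresolvable records get
# method NA rather than an error so apply_exclusions() can route them.
resolve_anchors <- function(cohort, discrepancy_limit_days = 10,
                            cm_per_week = 1,
                            days_per_month = DAYS_PER_MONTH) {
  n <- nrow(cohort)
  ref_date <- as.Date(rep(NA, n))
  ga_days <- rep(NA_integer_, n)
  method <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ev <- list(
      ultrasound_ga_weeks   = cohort$us_ga_weeks[i],
      ultrasound_date       = cohort$us_date[i],
      lmp_date              = cohort$lmp_date[i],
      fundal_height_cm      = cohort$fundal_height_cm[i],
      maternal_recall_months = cohort$recall_months[i],
      measurement_date      = cohort$enrollment_date[i]
    )
    a <- tryCatch(
      best_ga_anchor(ev, discrepancy_limit_days, cm_per_week, days_per_month),
      anccov_ga_unresolvable = function(e) NULL,
      anccov_ga_invalid_evidence = function(e) NULL
    )
    if (!is.null(a)) {
      ref_date[i] <- a$reference_date
      ga_days[i] <- a$ga_at_reference_days
      method[i] <- a$method
    }
  }
  tibble::tibble(
    woman_id = cohort$woman_id,
    ga_ref_date = ref_date,
    ga_ref_days = ga_days,
    ga_method = method
  )
}
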