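# builders for small hand-constructed cohorts and a brute-force retention
# oracle kept deliberately independent of the package implementation

make_cohort <- function(n = 1, woman_id = sprintf("A%03d", seq_len(n)),
                        enrollment_date = as.Date("2019-03-01"),
                        us_ga_weeks = NA_real_, us_date = as.Date(NA),
                        lmp_date = as.Date("2019-01-01"),
                        fundal_height_cm = NA_real_,
                        recall_months = NA_integer_,
                        self_visits_enroll = 0L,
                        delivery_date = as.Date("2019-09-20"),
                        outcome = "live_birth",
                        ltfu = FALSE, ltfu_date = as.Date(NA)) {
  tibble::tibble(
    woman_id = woman_id,
    enrollment_date = rep_len(enrollment_date, n),
    us_ga_weeks = rep_len(us_ga_weeks, n),
    us_date = rep_len(us_date, n),
    lmp_date = rep_len(lmp_date, n),
    fundal_height_cm = rep_len(fundal_height_cm, n),
    recall_months = rep_len(recall_months, n),
    self_visits_enroll = rep_len(as.integer(self_visits_enroll), n),
    delivery_date = rep_len(delivery_date, n),
    outcome = rep_len(outcome, n),
    ltfu = rep_len(ltfu, n),
    ltfu_date = rep_len(ltfu_date, n),
    age_years = 27, district = "District A", literate = TRUE,
    wealth_q = 3L, ethnicity = "Amhara", primiparous = FALSE,
    hist_stillbirth = FALSE, hist_preterm = FALSE, walk_minutes = 60)
}

make_visits <- function(woman_id, visit_date, source = "chart_prospective") {
  tibble::tibble(woman_id = woman_id,
                 visit_date = as.Date(visit_date),
                 source = rep_len(source, length(woman_id)))
}

make_flags <- function(patterns, delivery_ga_weeks = 39) {
  m <- t(vapply(strsplit(patterns, ""), function(ch) ch == "T", logical(4)))
  tibble::tibble(
    woman_id = sprintf("F%03d", seq_along(patterns)),
    w1 = m[, 1], w2 = m[, 2], w3 = m[, 3], w4 = m[, 4],
    delivery_ga_weeks = rep_len(delivery_ga_weeks, length(patterns)))
}

random_flags <- function(n) {
  tibble::tibble(
    woman_id = sprintf("R%04d", seq_len(n)),
    w1 = runif(n) < 0.8, w2 = runif(n) < 0.6,
    w3 = runif(n) < 0.5, w4 = runif(n) < 0.3,
    delivery_ga_weeks = ifelse(runif(n) < 0.15, 34, 39))
}

# direct per-woman enumeration of the retention definitions
oracle_sequential <- function(flags, x) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(flags))) {
    att <- c(flags$w1[i], flags$w2[i], flags$w3[i], flags$w4[i])
    in_denom <- att[x]
    if (x == 3 && flags$delivery_ga_weeks[i] < 36) in_denom <- FALSE
    if (!in_denom) next
    den <- den + 1L
    returned <- FALSE
    for (k in (x + 1):4) if (att[k]) returned <- TRUE
    if (returned) num <- num + 1L
  }
  c(num = num, den = den)
}

oracle_cumulative <- function(flags, k) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(flags))) {
    if (k == 4 && flags$delivery_ga_weeks[i] < 36) next
    den <- den + 1L
    att <- c(flags$w1[i], flags$w2[i], flags$w3[i], flags$w4[i])
    if (all(att[1:k])) num <- num + 1L
  }
  c(num = num, den = den)
}
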