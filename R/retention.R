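#' Retention across ANC gestational-age windows
#'
#' The four recommended visit windows, in gestational age: ANC 1 before 16
#' weeks, ANC 2 from 16 to <28 weeks, ANC 3 from 28 to <36 weeks, ANC 4 at
#' 36 weeks or later. Bounds are half-open and evaluated on integer GA
#' days (16 weeks = 112 days, 28 = 196, 36 = 252), so a visit at exactly
#' 16.0 weeks belongs to window 2.
#'
#' Two retention summaries:
#' * **Sequential** retention after window X (X = 1, 2, 3): among women
#'   who attended window X, the proportion who attended any later window.
#'   A woman who attended ANC 2, skipped ANC 3 and returned for ANC 4
#'   counts as retained after ANC 2. For X = 3 the denominator excludes
#'   women who delivered before 36 weeks, who never had a window 4.
#' * **Cumulative** retention up to window k (k = 1..4): the proportion of
#'   the whole subcohort who attended windows 1..k without a gap; for
#'   k = 4 the denominator again excludes deliveries before 36 weeks.
#'
#' @name retention
NULL

# window lower bounds in GA days; window k is [WINDOW_LO[k], WINDOW_LO[k+1])
WINDOW_LO_DAYS <- c(0L, 112L, 196L, 252L)

window_of_ga_days <- function(ga_days) {
  findInterval(ga_days, WINDOW_LO_DAYS)
}

#' Per-woman window-attendance flags
#'
#' Maps each dated prospective visit to its window by GA at the visit
#' date, under the woman's dating anchor. The window-1 flag is
#' additionally set when the woman self-reported any pre-enrollment visits:
#' in the early-enrollment subcohort (enrolled before 13 weeks) those
#' undated visits necessarily fall before 16 weeks.
#'
#' @param cohort A subcohort tibble with anchor columns (from
#'   [apply_exclusions()] / [select_subcohort()]).
#' @param visits A visits tibble; only `chart_prospective` rows are used.
#' @return A tibble `woman_id`, `w1`..`w4` (logical), `delivery_ga_weeks`.
#' @export
assign_windows <- function(cohort, visits) {
  visits <- validate_visits(visits)
  pro <- visits[visits$source == "chart_prospective" &
                  visits$woman_id %in% cohort$woman_id, ]
  pro <- dplyr::distinct(pro, .data$woman_id, .data$visit_date)
  idx <- match(pro$woman_id, cohort$woman_id)
  ga_days <- cohort$ga_ref_days[idx] +
    as.integer(pro$visit_date - cohort$ga_ref_date[idx])
  if (any(ga_days < 0)) {
    bad <- pro$woman_id[which(ga_days < 0)[1]]
    stop_anccov(paste0("visit before conception for woman ", bad),
                "anccov_invalid")
  }
  after_delivery <- !is.na(cohort$delivery_date[idx]) &
    pro$visit_date > cohort$delivery_date[idx]
  if (any(after_delivery)) {
    bad <- pro$woman_id[which(after_delivery)[1]]
    stop_anccov(paste0("visit after delivery for woman ", bad),
                "anccov_invalid")
  }
  win <- window_of_ga_days(ga_days)

  flags <- tibble::tibble(
    woman_id = cohort$woman_id,
    w1 = cohort$woman_id %in% pro$woman_id[win == 1] |
      (!is.na(cohort$self_visits_enroll) & cohort$self_visits_enroll > 0),
    w2 = cohort$woman_id %in% pro$woman_id[win == 2],
    w3 = cohort$woman_id %in% pro$woman_id[win == 3],
    w4 = cohort$woman_id %in% pro$woman_id[win == 4],
    delivery_ga_weeks = cohort$ga_delivery_weeks
  )
  flags
}

flags_matrix <- function(flags) {
  as.matrix(flags[, c("w1", "w2", "w3", "w4")])
}

#' Sequential retention after each window
#'
#' @param flags A window-flags tibble from [assign_windows()].
#' @param after Windows to compute retention after; subset of 1:3. There
#'   is no window after ANC 4, so `after = 4` is refused.
#' @param level Confidence level for the Agresti-Coull intervals.
#' @return A tibble of labelled retention estimates.
#' @export
sequential_retention <- function(flags, after = 1:3, level = 0.95) {
  if (any(after == 4)) {
    stop_anccov("no window follows ANC 4; sequential retention after it is undefined",
                "anccov_invalid")
  }
  stopifnot(all(after %in% 1:3))
  m <- flags_matrix(flags)
  rows <- lapply(after, function(x) {
    denom <- m[, x]
    if (x == 3) {
      # women delivering before 36 weeks never had a window 4 to return to
      denom <- denom & flags$delivery_ga_weeks >= 36
    }
    later <- rowSums(m[, (x + 1):4, drop = FALSE]) > 0
    if (sum(denom) == 0) {
      stop_anccov(sprintf("undefined estimate: no women in the ANC %d denominator", x),
                  "anccov_undefined")
    }
    est <- agresti_coull(sum(denom & later), sum(denom), level)
    dplyr::bind_cols(
      tibble::tibble(label = sprintf("retention after ANC %d", x)), est)
  })
  dplyr::bind_rows(rows)
}

#' Cumulative retention up to each window
#'
#' @inheritParams sequential_retention
#' @param upto Windows to accumulate to; subset of 1:4.
#' @return A tibble of labelled retention estimates.
#' @export
cumulative_retention <- function(flags, upto = 1:4, level = 0.95) {
  stopifnot(all(upto %in% 1:4))
  m <- flags_matrix(flags)
  rows <- lapply(upto, function(k) {
    in_denom <- if (k == 4) flags$delivery_ga_weeks >= 36 else
      rep(TRUE, nrow(flags))
    if (sum(in_denom) == 0) {
      stop_anccov("undefined estimate: empty denominator", "anccov_undefined")
    }
    chain <- rowSums(m[, 1:k, drop = FALSE]) == k
    est <- agresti_coull(sum(chain & in_denom), sum(in_denom), level)
    dplyr::bind_cols(
      tibble::tibble(label = sprintf("retention in ANC 1..%d", k)), est)
  })
  dplyr::bind_rows(rows)
}

#' Attendance-pattern flow table
#'
#' Counts of the 16 possible window-attendance patterns (the data behind
#' an alluvial retention plot). Patterns are `T`/`F` strings in window
#' order; counts sum to the cohort size, and the per-window margins equal
#' the per-window attendance counts.
#'
#' @param flags A window-flags tibble.
#' @return A tibble `pattern` (16 rows, `"TTTT"` .. `"FFFF"`), `count`.
#' @export
flow_table <- function(flags) {
  all_patterns <- apply(expand.grid(rep(list(c(TRUE, FALSE)), 4))[, 4:1],
                        1, function(r) paste(ifelse(r, "T", "F"), collapse = ""))
  all_patterns <- sort(unique(all_patterns), decreasing = TRUE)
  m <- flags_matrix(flags)
  pat <- if (nrow(m) == 0) character(0) else
    apply(m, 1, function(r) paste(ifelse(r, "T", "F"), collapse = ""))
  tab <- table(factor(pat, levels = all_patterns))
  tibble::tibble(pattern = names(tab), count = as.integer(tab))
}
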