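#' ANC coverage estimation
#'
#' Coverage of at least one, four, and eight antenatal-care visits is the
#' proportion of women whose total visit count reaches the threshold,
#' where the total combines visits prospectively abstracted from facility
#' charts after enrollment with the woman's self-reported count of visits
#' before enrollment. Proportions carry Agresti-Coull 95% confidence
#' intervals.
#'
#' @name coverage
NULL

#' Assemble per-woman visit counts
#'
#' For each woman: `n_prospective` is the number of distinct
#' `chart_prospective` visit dates on or after enrollment (same-day
#' duplicate chart rows collapse to one visit — a visit is a day);
#' `n_pre_enrollment_selfreport` is the self-reported count at enrollment;
#' `n_total` is their sum. `chart_retrospective` records are excluded from
#' totals (they serve only the self-report agreement check). A
#' `chart_prospective` visit dated before enrollment is a data error: it
#' is reassigned to the pre-enrollment pool only when the self-report
#' count is zero, otherwise dropped, with a warning either way —
#' double-counting is the worse failure mode given the combination rule.
#'
#' @param cohort A cohort tibble (every woman gets a row, visits or not).
#' @param visits A validated visits tibble.
#' @return A tibble with columns `woman_id`, `n_pre_enrollment_selfreport`,
#'   `n_prospective`, `n_total`.
#' @export
assemble_visit_counts <- function(cohort, visits) {
  visits <- validate_visits(visits)
  pro <- visits[visits$source == "chart_prospective" &
                  visits$woman_id %in% cohort$woman_id, ]
  pro <- dplyr::distinct(pro, .data$woman_id, .data$visit_date)
  pro <- dplyr::left_join(
    pro, cohort[, c("woman_id", "enrollment_date", "self_visits_enroll")],
    by = "woman_id")

  early <- pro$visit_date < pro$enrollment_date
  reassign <- integer(0)
  if (any(early)) {
    zero_self <- early & pro$self_visits_enroll == 0
    rlang::warn(sprintf(
      "%d prospective visit(s) dated before enrollment: %d reassigned to the pre-enrollment pool, %d dropped",
      sum(early), sum(zero_self), sum(early & !zero_self)))
    reassign <- table(pro$woman_id[zero_self])
    pro <- pro[!early, ]
  }

  n_pro <- dplyr::count(pro, .data$woman_id, name = "n_prospective")
  out <- tibble::tibble(
    woman_id = cohort$woman_id,
    n_pre_enrollment_selfreport = as.integer(cohort$self_visits_enroll)
  )
  if (length(reassign) > 0) {
    idx <- match(names(reassign), out$woman_id)
    out$n_pre_enrollment_selfreport[idx] <-
      out$n_pre_enrollment_selfreport[idx] + as.integer(reassign)
  }
  out <- dplyr::left_join(out, n_pro, by = "woman_id")
  out$n_prospective <- dplyr::coalesce(out$n_prospective, 0L)
  out$n_total <- out$n_pre_enrollment_selfreport + out$n_prospective
  out
}

#' Agresti-Coull binomial confidence interval
#'
#' With \eqn{z} the standard-normal quantile at \eqn{(1+level)/2}:
#' \eqn{\tilde n = n + z^2}, \eqn{\tilde p = (x + z^2/2)/\tilde n}, and the
#' interval is \eqn{\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}},
#' clipped to \eqn{[0,1]}. The point estimate stays the raw proportion
#' \eqn{x/n}. \eqn{z} is the exact quantile (about 1.959964 at the default
#' level), not 1.96.
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `numerator`, `denominator`, `proportion`,
#'   `ci_low`, `ci_high`, `level`.
#' @export
#' @examples
#' agresti_coull(146, 150) # 97.3% (93.1-99.2)
agresti_coull <- function(x, n, level = 0.95) {
  if (any(n < 1)) {
    stop_anccov("undefined estimate: zero denominator", "anccov_undefined")
  }
  if (any(x < 0 | x > n)) {
    stop_anccov("successes must lie in [0, n]", "anccov_invalid")
  }
  z <- qnorm((1 + level) / 2)
  n_t <- n + z^2
  p_t <- (x + z^2 / 2) / n_t
  hw <- z * sqrt(p_t * (1 - p_t) / n_t)
  tibble::tibble(
    numerator = as.integer(x),
    denominator = as.integer(n),
    proportion = x / n,
    ci_low = pmax(0, p_t - hw),
    ci_high = pmin(1, p_t + hw),
    level = level
  )
}

#' Coverage indicators at visit-count thresholds
#'
#' One Agresti-Coull estimate per threshold (default: at least 1, 4, and 8
#' visits) over a common denominator, plus the zero-visit proportion.
#'
#' @param counts A visit-count tibble from [assemble_visit_counts()].
#' @param thresholds Positive, sorted visit-count thresholds.
#' @param level Confidence level.
#' @return A tibble of labelled coverage estimates.
#' @export
coverage_indicators <- function(counts, thresholds = c(1, 4, 8),
                                level = 0.95) {
  if (nrow(counts) == 0) {
    stop_anccov("undefined estimate: empty cohort", "anccov_undefined")
  }
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  n <- nrow(counts)
  rows <- lapply(thresholds, function(k) {
    est <- agresti_coull(sum(counts$n_total >= k), n, level)
    dplyr::bind_cols(tibble::tibble(indicator = sprintf(">=%d visits", k)), est)
  })
  zero <- dplyr::bind_cols(
    tibble::tibble(indicator = "0 visits"),
    agresti_coull(sum(counts$n_total == 0), n, level))
  dplyr::bind_rows(dplyr::bind_rows(rows), zero)
}

#' Distribution of total visit counts
#'
#' @param counts A visit-count tibble.
#' @return A tibble `visits`, `frequency`, `percent`; frequencies sum to
#'   the denominator and percentages to 100 within rounding.
#' @export
visit_distribution <- function(counts) {
  d <- dplyr::count(counts, visits = .data$n_total, name = "frequency")
  d$percent <- 100 * d$frequency / sum(d$frequency)
  d
}

#' Median and interquartile range of visit counts
#'
#' Quartiles use the inverse-empirical-CDF convention (`quantile`
#' `type = 1`) by default, which returns observed integer counts and so
#' matches integer reporting; the convention is configurable.
#'
#' @param counts A visit-count tibble (or bare numeric vector).
#' @param type Quantile type passed to [stats::quantile()].
#' @return A one-row tibble `median`, `q1`, `q3`.
#' @export
median_iqr <- function(counts, type = 1) {
  x <- if (is.data.frame(counts)) counts$n_total else counts
  if (length(x) == 0) {
    stop_anccov("undefined estimate: empty counts", "anccov_undefined")
  }
  q <- quantile(x, c(0.25, 0.75), type = type, names = FALSE)
  tibble::tibble(median = median(x), q1 = q[1], q3 = q[2])
}

#' Agreement between self-reported and chart-recorded visit counts
#'
#' For women with both a self-reported count at enrollment and a
#' retrospective chart count, reports the exact-agreement fraction and the
#' over- and under-reporting fractions (which sum to 1).
#'
#' @param paired A tibble with columns `reported` and `chart`.
#' @return A tibble `category` (`exact`, `over`, `under`), `n`, `fraction`.
#' @export
selfreport_agreement <- function(paired) {
  if (nrow(paired) == 0) {
    stop_anccov("undefined estimate: no paired counts", "anccov_undefined")
  }
  n <- nrow(paired)
  tibble::tibble(
    category = c("exact", "over", "under"),
    n = c(sum(paired$reported == paired$chart),
          sum(paired$reported > paired$chart),
          sum(paired$reported < paired$chart))
  ) |>
    dplyr::mutate(fraction = .data$n / !!n)
}
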