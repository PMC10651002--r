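#' Loss-to-follow-up sensitivity scenarios
#'
#' Attrition before delivery can bias coverage upward if lost women attend
#' less than women followed to delivery. Rather than imputing, the
#' analysis brackets the estimates with deterministic scenarios that
#' assume lost women's coverage is some fraction of the completers'.
#'
#' * For "at least one visit": lost women count as covered only if they
#'   had a recorded visit before being lost; the rest are assumed never to
#'   have attended.
#' * For "four or more visits": a lost woman with `v` visits at censoring
#'   counts fully if `v >= 4`; otherwise she contributes
#'   `f * Phat(total >= 4 | total >= v)`, where `Phat` is the empirical
#'   conditional among completers and `f` in `[0, 1]` attenuates the
#'   completers' coverage (0% to 90% in the reported sweep).
#'
#' @name ltfu-sensitivity
NULL

#' Scenario: lost women without a recorded visit never attended
#'
#' @param completers Visit-count tibble for women followed to delivery.
#' @param lost Visit-count tibble for lost women (counts as recorded at
#'   censoring).
#' @param level Confidence level.
#' @return A one-row coverage-estimate tibble with a `label` column.
#' @export
scenario_any_visit <- function(completers, lost, level = 0.95) {
  n <- nrow(completers) + nrow(lost)
  if (n == 0) {
    stop_anccov("undefined estimate: empty combined denominator",
                "anccov_undefined")
  }
  x <- sum(completers$n_total >= 1) + sum(lost$n_total >= 1)
  dplyr::bind_cols(
    tibble::tibble(label = "any_visit", f = NA_real_),
    agresti_coull(x, n, level))
}

#' Scenario: lost women's four-plus coverage attenuated by f
#'
#' The expected numerator keeps its exact (fractional) value for the
#' point proportion; the Agresti-Coull interval is computed on the
#' half-up-rounded numerator.
#'
#' @inheritParams scenario_any_visit
#' @param f Attenuation fraction in `[0, 1]` applied to the conditional
#'   completer coverage.
#' @return A one-row coverage-estimate tibble with `label` and `f`
#'   columns; `proportion` is the exact expected proportion.
#' @export
scenario_four_plus <- function(completers, lost, f, level = 0.95) {
  stopifnot(f >= 0, f <= 1)
  n <- nrow(completers) + nrow(lost)
  if (n == 0) {
    stop_anccov("undefined estimate: empty combined denominator",
                "anccov_undefined")
  }
  comp4 <- sum(completers$n_total >= 4)
  overall <- comp4 / max(1, nrow(completers))
  contrib <- vapply(lost$n_total, function(v) {
    if (v >= 4) return(1)
    eligible <- completers$n_total >= v
    if (!any(eligible)) {
      rlang::inform(sprintf(
        "no completer with >= %d visits; falling back to overall completer coverage", v))
      return(f * overall)
    }
    f * mean(completers$n_total[eligible] >= 4)
  }, numeric(1))
  expected_x <- comp4 + sum(contrib)
  est <- agresti_coull(round_half_up(expected_x), n, level)
  est$proportion <- expected_x / n
  dplyr::bind_cols(tibble::tibble(label = "four_plus", f = f), est)
}

#' Run a set of sensitivity scenarios
#'
#' @inheritParams scenario_any_visit
#' @param specs A data frame with columns `outcome` (`"any_visit"` or
#'   `"four_plus"`) and `f` (used by `four_plus`).
#' @return A tibble of labelled scenario estimates, one row per spec.
#' @export
run_scenarios <- function(completers, lost, specs, level = 0.95) {
  stopifnot(nrow(specs) > 0)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    switch(specs$outcome[i],
      any_visit = scenario_any_visit(completers, lost, level),
      four_plus = scenario_four_plus(completers, lost, specs$f[i], level),
      stop_anccov(paste0("unknown scenario outcome: ", specs$outcome[i]),
                  "anccov_config"))
  })
  dplyr::bind_rows(rows)
}
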