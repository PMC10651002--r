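#' End-to-end pipeline and group comparability
#'
#' [run_pipeline()] chains the whole analysis — exclusions, gestational
#' dating, subcohort selection, coverage, retention, loss-to-follow-up
#' scenarios, baseline comparability — and writes one tidy CSV per stage
#' plus a `run.json` capturing the frozen configuration and tallies, so a
#' run is reproducible from its output directory alone.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param cohort_path,visits_path Input CSVs; alternatively supply
#'   `sim_config` to simulate instead of reading.
#' @param sim_config A [sim_config()] used when no input paths are given.
#' @param subcohort_ga_threshold_weeks Enrollment-GA cut for the primary
#'   subcohort (default 13).
#' @param thresholds Coverage visit-count thresholds.
#' @param level Confidence level.
#' @param scenario_f Attenuation sweep for the four-plus scenarios.
#' @param scenario_scope `"subcohort"` (default) restricts the
#'   sensitivity analysis to lost women who enrolled before the
#'   subcohort threshold; `"full"` uses all lost women.
#' @param discrepancy_limit_days GA dating discrepancy limit.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Master seed (simulation and run record).
#' @return A classed list of settings.
#' @export
run_config <- function(cohort_path = NULL, visits_path = NULL,
                       sim_config = NULL,
                       subcohort_ga_threshold_weeks = 13,
                       thresholds = c(1, 4, 8),
                       level = 0.95,
                       scenario_f = c(0, 0.45, 0.9),
                       scenario_scope = c("subcohort", "full"),
                       discrepancy_limit_days = 10,
                       out_dir = NULL,
                       seed = 1L) {
  scenario_scope <- match.arg(scenario_scope)
  if (is.null(sim_config) && (is.null(cohort_path) || is.null(visits_path))) {
    stop_anccov("supply cohort_path and visits_path, or a sim_config",
                "anccov_config")
  }
  structure(as.list(environment()), class = "anccov_run_config")
}

#' Run the full analysis pipeline
#'
#' @param config A [run_config()].
#' @return The report bundle, invisibly: a list with `tally`, `coverage`,
#'   `distribution`, `median_iqr`, `flags`, `retention`, `flow`,
#'   `sensitivity`, `comparability`, `agreement` (when retrospective chart
#'   data exist), and the input tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "anccov_run_config"))
  if (!is.null(config$sim_config)) {
    sim <- simulate_cohort(config$sim_config, config$seed)
    cohort <- sim$cohort; visits <- sim$visits
  } else {
    cohort <- read_cohort(config$cohort_path)
    visits <- read_visits(config$visits_path)
  }

  excl <- apply_exclusions(cohort, config$discrepancy_limit_days)
  sub <- select_subcohort(excl$analysis, config$subcohort_ga_threshold_weeks)
  counts <- assemble_visit_counts(sub, visits)

  coverage <- coverage_indicators(counts, config$thresholds, config$level)
  distribution <- visit_distribution(counts)
  miqr <- median_iqr(counts)

  flags <- assign_windows(sub, visits)
  retention <- dplyr::bind_rows(
    dplyr::mutate(sequential_retention(flags, level = config$level),
                  kind = "sequential", .before = 1),
    dplyr::mutate(cumulative_retention(flags, level = config$level),
                  kind = "cumulative", .before = 1))
  flow <- flow_table(flags)

  lost <- excl$ltfu
  if (config$scenario_scope == "subcohort" && nrow(lost) > 0) {
    lost <- lost[!is.na(lost$ga_enroll_weeks) &
                   lost$ga_enroll_weeks < config$subcohort_ga_threshold_weeks, ]
  }
  lost_counts <- assemble_visit_counts(lost, visits)
  specs <- dplyr::bind_rows(
    tibble::tibble(outcome = "any_visit", f = NA_real_),
    tibble::tibble(outcome = "four_plus", f = config$scenario_f))
  sensitivity <- run_scenarios(counts, lost_counts, specs, config$level)

  comparability <- compare_groups(excl$analysis,
                                  config$subcohort_ga_threshold_weeks)

  agreement <- NULL
  paired <- selfreport_pairs(cohort, visits)
  if (nrow(paired) > 0) agreement <- selfreport_agreement(paired)

  bundle <- list(
    tally = excl$tally, coverage = coverage, distribution = distribution,
    median_iqr = miqr, flags = flags, retention = retention, flow = flow,
    sensitivity = sensitivity, comparability = comparability,
    agreement = agreement, cohort = cohort, visits = visits,
    subcohort = sub, counts = counts, config = config)

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

# pair self-reported counts with retrospective chart counts where the
# latter exist (the subgroup with retrospective abstraction)
selfreport_pairs <- function(cohort, visits) {
  retro <- visits[visits$source == "chart_retrospective", ]
  if (nrow(retro) == 0) {
    return(tibble::tibble(woman_id = character(),
                          reported = integer(), chart = integer()))
  }
  retro <- dplyr::distinct(retro, .data$woman_id, .data$visit_date)
  chart <- dplyr::count(retro, .data$woman_id, name = "chart")
  out <- dplyr::inner_join(
    tibble::tibble(woman_id = cohort$woman_id,
                   reported = as.integer(cohort$self_visits_enroll)),
    chart, by = "woman_id")
  out$chart <- as.integer(out$chart)
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name), na = "")
  w(bundle$tally, "exclusions.csv")
  w(bundle$coverage, "coverage.csv")
  w(bundle$distribution, "distribution.csv")
  w(bundle$retention, "retention.csv")
  w(bundle$flow, "flow.csv")
  w(bundle$sensitivity, "sensitivity.csv")
  w(bundle$comparability, "comparability.csv")
  cfg <- bundle$config
  run <- list(
    seed = cfg$seed,
    subcohort_ga_threshold_weeks = cfg$subcohort_ga_threshold_weeks,
    thresholds = cfg$thresholds, level = cfg$level,
    scenario_f = cfg$scenario_f, scenario_scope = cfg$scenario_scope,
    discrepancy_limit_days = cfg$discrepancy_limit_days,
    simulated = !is.null(cfg$sim_config),
    sim_config = if (!is.null(cfg$sim_config))
      unclass(cfg$sim_config)[!vapply(unclass(cfg$sim_config), is.null, logical(1))],
    tally = as.list(bundle$tally),
    package_version = as.character(utils::packageVersion("anccov")))
  jsonlite::write_json(run, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Baseline comparability between enrollment groups
#'
#' Compares covariates between women enrolled before and at/after the
#' GA threshold: Welch t-test for continuous covariates; for categorical
#' covariates a chi-squared test without continuity correction, replaced
#' by Fisher's exact test whenever any expected cell count is below 5.
#'
#' @param cohort An analysis cohort with `ga_enroll_weeks`.
#' @param threshold_weeks Grouping threshold (default 13).
#' @return A tibble: `variable`, `type`, `test`, `p_value`, and group
#'   summaries (`mean (SD)` or `n (%)` of the reference category).
#' @export
compare_groups <- function(cohort, threshold_weeks = 13) {
  g <- cohort$ga_enroll_weeks < threshold_weeks
  continuous <- intersect(c("age_years", "walk_minutes"), names(cohort))
  categorical <- intersect(
    c("district", "literate", "wealth_q", "ethnicity", "primiparous",
      "hist_stillbirth", "hist_preterm"), names(cohort))

  summ_cont <- function(x) sprintf("%.1f (%.1f)",
                                   mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    if (all(is.na(x))) {
      rows[[v]] <- tibble::tibble(variable = v, type = "continuous",
                                  group_early = NA_character_,
                                  group_late = NA_character_,
                                  test = "none (all missing)",
                                  p_value = NA_real_)
      next
    }
    constant <- isTRUE(sd(x, na.rm = TRUE) == 0)
    p <- if (constant) NA_real_ else t.test(x[g], x[!g])$p.value
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      group_early = summ_cont(x[g]), group_late = summ_cont(x[!g]),
      test = if (constant) "none (constant)" else "t", p_value = p)
  }
  for (v in categorical) {
    x <- cohort[[v]]
    if (all(is.na(x))) {
      rows[[v]] <- tibble::tibble(variable = v, type = "categorical",
                                  group_early = NA_character_,
                                  group_late = NA_character_,
                                  test = "none (all missing)",
                                  p_value = NA_real_)
      next
    }
    tab <- table(factor(x), g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test <- "fisher"
      p <- fisher.test(tab)$p.value
    } else {
      test <- "chi-squared"
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    ref <- rownames(tab)[nrow(tab)]
    summ_cat <- function(grp) {
      n <- sum(x[grp] == ref, na.rm = TRUE)
      sprintf("%d (%.1f)", n, 100 * n / sum(!is.na(x[grp])))
    }
    rows[[v]] <- tibble::tibble(
      variable = v, type = "categorical",
      group_early = summ_cat(g), group_late = summ_cat(!g),
      test = test, p_value = p)
  }
  dplyr::bind_rows(rows)
}

#' Render the report tables
#'
#' Formats the bundle's coverage and retention tables as markdown and/or
#' CSV. The renderer only formats — every number is taken verbatim from
#' the bundle; percentages are rounded to one decimal, halves away from
#' zero.
#'
#' @param bundle A bundle from [run_pipeline()].
#' @param format `"markdown"`, `"csv"`, or both.
#' @param out_dir Directory to write into.
#' @return Paths of the written files, invisibly.
#' @export
render_report <- function(bundle, format = c("markdown", "csv"),
                          out_dir = ".") {
  bad <- setdiff(format, c("markdown", "csv"))
  if (length(bad) > 0) {
    stop_anccov(paste0("unknown report format: ", paste(bad, collapse = ", ")),
                "anccov_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt_row <- function(d) {
    tibble::tibble(
      label = d[[1]],
      N = d$denominator, n = d$numerator,
      pct = round_half_up(100 * d$proportion, 1),
      ci_low = round_half_up(100 * d$ci_low, 1),
      ci_high = round_half_up(100 * d$ci_high, 1))
  }
  cov <- fmt_row(bundle$coverage)
  paths <- character(0)
  if ("csv" %in% format) {
    p <- file.path(out_dir, "report_coverage.csv")
    readr::write_csv(cov, p)
    paths <- c(paths, p)
  }
  lines <- c("# ANC coverage", "",
             "| Indicator | N | n | % (95% CI) |",
             "|---|---|---|---|",
             sprintf("| %s | %d | %d | %.1f (%.1f-%.1f) |",
                     cov$label, cov$N, cov$n, cov$pct, cov$ci_low, cov$ci_high),
             "")
  if (!is.null(bundle$retention) && nrow(bundle$retention) > 0) {
    ret <- fmt_row(bundle$retention[, -1])
    ret$kind <- bundle$retention$kind
    if ("csv" %in% format) {
      p <- file.path(out_dir, "report_retention.csv")
      readr::write_csv(ret, p)
      paths <- c(paths, p)
    }
    lines <- c(lines, "# ANC retention", "",
               "| Retention | N | n | % (95% CI) |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %.1f (%.1f-%.1f) |",
                       ret$label, ret$N, ret$n, ret$pct, ret$ci_low,
                       ret$ci_high),
               "")
  } else {
    lines <- c(lines, "_Retention section omitted: no retention results in bundle._")
  }
  if ("markdown" %in% format) {
    p <- file.path(out_dir, "report.md")
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
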