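#' Synthetic pregnancy-cohort simulator
#'
#' Generates cohort and visit tables with the statistical structure the
#' downstream estimators assume, together with the per-woman truth and the
#' closed-form parameters it implies, so every estimator can be validated
#' against known ground truth without any external data.
#'
#' Window attendance follows a two-state first-order (Markov) chain over
#' the four ANC windows with prescribed marginals and a persistence
#' parameter; each attended window yields exactly one dated visit placed
#' uniformly (in days) inside the window and before delivery. Visits dated
#' before enrollment are not emitted as prospective chart rows: their
#' count passes through the self-report error process into the enrollment
#' self-report, and (for a subset of women) they are additionally emitted
#' as retrospective chart rows so the self-report agreement check has
#' paired data.
#'
#' @name synthetic-cohort
NULL

#' Simulation configuration
#'
#' Defaults describe the demonstration profile: a rural Ethiopian
#' pregnancy cohort with ~7% first-trimester enrollment, window
#' attendance falling from ~81% to ~29%, ~2.7% miscarriages, ~1.4%
#' implausible documented GA, ~6.3% loss to follow-up, and self-reports
#' agreeing exactly with chart counts about half the time. This is
#' calibration by construction, not inference.
#'
#' @param n_women Number of pregnancies.
#' @param frac_enroll_early Fraction enrolling before 13 weeks.
#' @param enroll_early_range_weeks,enroll_late_range_weeks Uniform GA
#'   ranges (weeks) for early and late enrollment.
#' @param delivery_ga_mean_weeks,delivery_ga_sd_weeks,delivery_ga_range_weeks
#'   Truncated-normal delivery GA (weeks).
#' @param miscarriage_rate Fraction with pregnancy loss before 28 weeks.
#' @param implausible_ga_rate Fraction given out-of-range documented GA
#'   (split between enrollment GA 0 and delivery GA >=46 weeks).
#' @param window_attendance_probs Marginal attendance probability for each
#'   of the four ANC windows.
#' @param dropout_persistence First-order dependence in `[0,1]`: the
#'   conditional attendance probability given the previous window was
#'   attended is `p + dropout_persistence * (1 - p)`; 0 is independence.
#' @param selfreport_exact_prob Probability a self-reported count equals
#'   the true pre-enrollment count.
#' @param selfreport_error_spread Maximum absolute self-report error
#'   (uniform over nonzero offsets, clipped at zero).
#' @param ltfu_rate Fraction lost to follow-up (censored before delivery).
#' @param retro_chart_fraction Fraction of women whose pre-enrollment
#'   visits are also abstracted retrospectively from charts.
#' @param us_prob,lmp_prob Probability an ultrasound / an LMP date is
#'   recorded.
#' @param evidence_noise_days Half-width (days) of the integer-uniform
#'   noise on recorded dating evidence; 0 makes documented GA exact.
#' @param enrollment_start,enrollment_end Calendar bounds on enrollment.
#' @return A validated config (classed list).
#' @export
sim_config <- function(n_women = 2303,
                       frac_enroll_early = 0.072,
                       enroll_early_range_weeks = c(5, 13),
                       enroll_late_range_weeks = c(13, 36),
                       delivery_ga_mean_weeks = 39.5,
                       delivery_ga_sd_weeks = 1.5,
                       delivery_ga_range_weeks = c(28, 46),
                       miscarriage_rate = 0.027,
                       implausible_ga_rate = 0.014,
                       window_attendance_probs = c(0.81, 0.59, 0.49, 0.29),
                       dropout_persistence = 0.1,
                       selfreport_exact_prob = 0.5,
                       selfreport_error_spread = 2,
                       ltfu_rate = 0.063,
                       retro_chart_fraction = 0.25,
                       us_prob = 0.3,
                       lmp_prob = 0.9,
                       evidence_noise_days = 3,
                       enrollment_start = as.Date("2018-12-01"),
                       enrollment_end = as.Date("2020-04-30")) {
  cfg <- as.list(environment())
  fracs <- c(frac_enroll_early, miscarriage_rate, implausible_ga_rate,
             window_attendance_probs, dropout_persistence,
             selfreport_exact_prob, ltfu_rate, retro_chart_fraction,
             us_prob, lmp_prob)
  if (any(fracs < 0 | fracs > 1)) {
    stop_anccov("all rates and probabilities must lie in [0, 1]",
                "anccov_config")
  }
  stopifnot(length(window_attendance_probs) == 4,
            n_women >= 0, selfreport_error_spread >= 0)
  # chain feasibility: marginal constraint must give a valid q0
  tr <- chain_transitions(window_attendance_probs, dropout_persistence)
  if (any(tr$q0 < 0 | tr$q0 > 1)) {
    stop_anccov("infeasible window marginals / persistence combination",
                "anccov_config")
  }
  structure(cfg, class = "anccov_sim_config")
}

# conditional attendance probabilities for transitions k -> k+1:
# q1 = P(attend k+1 | attended k) = p_{k+1} + rho (1 - p_{k+1});
# q0 solved so the marginal p_{k+1} holds. rho = 0 is independence.
chain_transitions <- function(p, rho) {
  q1 <- p[2:4] + rho * (1 - p[2:4])
  q0 <- (p[2:4] - p[1:3] * q1) / (1 - p[1:3])
  q0[p[1:3] == 1] <- 0 # irrelevant branch; marginal carried by q1
  list(q1 = q1, q0 = q0)
}

#' Closed-form truth implied by a simulation config
#'
#' Enumerates the 16 window-attendance patterns under the first-order
#' chain (ignoring delivery truncation) and returns the implied window
#' marginals, the probability of at least one attended window (= at least
#' one visit, since each attended window yields one visit), and the
#' cumulative-retention probabilities.
#'
#' @param config A [sim_config()].
#' @return A list: `window_marginals`, `p_any_visit`, `cumulative`
#'   (length 4), `pattern_probs` (16-row tibble).
#' @export
implied_truth <- function(config) {
  p <- config$window_attendance_probs
  tr <- chain_transitions(p, config$dropout_persistence)
  pats <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 4)))[, 1:4]
  colnames(pats) <- paste0("w", 1:4)
  prob <- apply(pats, 1, function(a) {
    pr <- if (a[1]) p[1] else 1 - p[1]
    for (k in 1:3) {
      q <- if (a[k]) tr$q1[k] else tr$q0[k]
      pr <- pr * if (a[k + 1]) q else 1 - q
    }
    pr
  })
  pattern_probs <- tibble::tibble(
    pattern = apply(pats, 1, function(r)
      paste(ifelse(r, "T", "F"), collapse = "")),
    prob = prob)
  list(
    window_marginals = p,
    p_any_visit = sum(prob[rowSums(pats) > 0]),
    cumulative = vapply(1:4, function(k)
      sum(prob[rowSums(pats[, 1:k, drop = FALSE]) == k]), numeric(1)),
    pattern_probs = pattern_probs
  )
}

#' Self-report error process
#'
#' With probability `exact_prob` the reported count equals the true
#' count; otherwise a nonzero integer error uniform on
#' `{-spread..-1, 1..spread}` is added and the result clipped at zero.
#'
#' @param true_count Non-negative integer vector of true pre-enrollment
#'   visit counts.
#' @param exact_prob Probability of exact agreement.
#' @param spread Maximum absolute error (non-negative integer); 0 forces
#'   exact reporting.
#' @return Integer vector of reported counts, same length as `true_count`.
#' @export
apply_selfreport_error <- function(true_count, exact_prob, spread) {
  stopifnot(all(true_count >= 0), spread >= 0)
  n <- length(true_count)
  if (n == 0) return(integer(0))
  exact <- runif(n) < exact_prob
  if (spread == 0) return(as.integer(true_count))
  err <- sample(c(-seq_len(spread), seq_len(spread)), n, replace = TRUE)
  out <- ifelse(exact, true_count, pmax(0L, true_count + err))
  as.integer(out)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a cohort
#'
#' Randomness flows through per-woman substreams derived from `seed`, so
#' the output is reproducible and appending a woman does not perturb the
#' others.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return A list `cohort` (cohort tibble), `visits` (visits tibble), and
#'   `truth`: per-woman true window flags, visit counts and delivery GA
#'   (`per_woman`), plus [implied_truth()] under `implied`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "anccov_sim_config"))
  n <- config$n_women
  tr <- chain_transitions(config$window_attendance_probs,
                          config$dropout_persistence)
  set.seed(seed)
  woman_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(woman_seeds[i])
    rows[[i]] <- simulate_woman(sprintf("W%05d", i), config, tr)
  }

  if (n == 0) {
    return(list(cohort = empty_cohort(), visits = empty_visits(),
                truth = list(per_woman = tibble::tibble(),
                             implied = implied_truth(config))))
  }

  # assemble once from plain per-woman lists (row-binding 20k one-row
  # tibbles is prohibitively slow)
  f <- function(name, how = c) do.call(how, lapply(rows, `[[`, name))
  cohort <- tibble::as_tibble(lapply(
    stats::setNames(nm = names(empty_cohort())),
    function(nm) f(nm)))
  for (d in c("enrollment_date", "us_date", "lmp_date", "delivery_date",
              "ltfu_date")) {
    cohort[[d]] <- as.Date(cohort[[d]], origin = "1970-01-01")
  }
  visits <- tibble::tibble(
    woman_id = f("visit_woman_id"),
    visit_date = as.Date(f("visit_ga_date"), origin = "1970-01-01"),
    source = f("visit_source"))
  truth <- tibble::as_tibble(lapply(
    stats::setNames(nm = c("woman_id", "true_w1", "true_w2", "true_w3",
                           "true_w4", "true_total_visits", "true_pre_count",
                           "true_enroll_ga_weeks", "true_delivery_ga_weeks",
                           "miscarriage", "implausible", "ltfu_truth")),
    function(nm) f(nm)))
  names(truth)[names(truth) == "ltfu_truth"] <- "ltfu"
  list(cohort = cohort, visits = visits,
       truth = list(per_woman = truth, implied = implied_truth(config)))
}

empty_cohort <- function() {
  tibble::tibble(
    woman_id = character(), enrollment_date = as.Date(character()),
    us_ga_weeks = numeric(), us_date = as.Date(character()),
    lmp_date = as.Date(character()), fundal_height_cm = numeric(),
    recall_months = integer(), self_visits_enroll = integer(),
    delivery_date = as.Date(character()), outcome = character(),
    ltfu = logical(), ltfu_date = as.Date(character()),
    age_years = numeric(), district = character(), literate = logical(),
    wealth_q = integer(), ethnicity = character(), primiparous = logical(),
    hist_stillbirth = logical(), hist_preterm = logical(),
    walk_minutes = numeric())
}

empty_visits <- function() {
  tibble::tibble(woman_id = character(),
                 visit_date = as.Date(character()),
                 source = character())
}

simulate_woman <- function(id, cfg, tr) {
  # enrollment GA (true, in days) and calendar anchor
  early <- runif(1) < cfg$frac_enroll_early
  rng <- if (early) cfg$enroll_early_range_weeks else cfg$enroll_late_range_weeks
  enroll_ga <- as.integer(round(runif(1, rng[1] * 7, rng[2] * 7 - 1)))
  enrollment_date <- cfg$enrollment_start +
    as.integer(floor(runif(1) *
      (as.integer(cfg$enrollment_end - cfg$enrollment_start) + 1)))

  # outcome class and delivery GA (days)
  u <- runif(1)
  implaus_variant <- NA_character_
  if (u < cfg$miscarriage_rate) {
    outcome <- "miscarriage"
    delivery_ga <- as.integer(round(runif(1, 10 * 7, 28 * 7 - 1)))
  } else if (u < cfg$miscarriage_rate + cfg$implausible_ga_rate) {
    outcome <- "live_birth"
    implaus_variant <- if (runif(1) < 0.5) "enroll" else "delivery"
    delivery_ga <- if (implaus_variant == "delivery") {
      # kept clear of the 46-week screen boundary so documented GA stays
      # out of range even under maximal evidence noise
      as.integer(round(runif(1, 46.5 * 7, 48 * 7)))
    } else {
      as.integer(round(7 * rtrunc_norm(1, cfg$delivery_ga_mean_weeks,
                                       cfg$delivery_ga_sd_weeks,
                                       cfg$delivery_ga_range_weeks[1],
                                       cfg$delivery_ga_range_weeks[2])))
    }
  } else {
    outcome <- if (runif(1) < 0.98) "live_birth" else "stillbirth"
    delivery_ga <- as.integer(round(7 * rtrunc_norm(
      1, cfg$delivery_ga_mean_weeks, cfg$delivery_ga_sd_weeks,
      cfg$delivery_ga_range_weeks[1], cfg$delivery_ga_range_weeks[2])))
  }
  enroll_ga <- min(enroll_ga, delivery_ga - 14L)
  enroll_ga <- max(enroll_ga, 7L)
  true_lmp <- enrollment_date - enroll_ga
  delivery_date <- true_lmp + delivery_ga

  # window attendance via the chain, truncated at delivery
  a <- logical(4)
  a[1] <- runif(1) < cfg$window_attendance_probs[1]
  for (k in 2:4) {
    q <- if (a[k - 1]) tr$q1[k - 1] else tr$q0[k - 1]
    a[k] <- runif(1) < q
  }
  attainable <- delivery_ga > WINDOW_LO_DAYS &
    delivery_ga > pmax(WINDOW_LO_DAYS, 28L) # visits not placed before 4 weeks GA
  a <- a & attainable

  # one dated visit per attended window, uniform in the window and
  # strictly before delivery
  visit_ga <- integer(0)
  hi_all <- c(112L, 196L, 252L, delivery_ga)
  lo_all <- pmax(WINDOW_LO_DAYS, 28L)
  for (k in which(a)) {
    lo <- lo_all[k]
    hi <- min(hi_all[k], delivery_ga)
    visit_ga <- c(visit_ga, lo + as.integer(floor(runif(1) * (hi - lo))))
  }
  visit_dates <- true_lmp + visit_ga

  pre <- visit_ga < enroll_ga
  true_pre_count <- sum(pre)
  reported <- apply_selfreport_error(true_pre_count,
                                     cfg$selfreport_exact_prob,
                                     cfg$selfreport_error_spread)
  retro <- runif(1) < cfg$retro_chart_fraction

  # loss to follow-up: censor uniformly between enrollment and delivery
  ltfu <- FALSE
  ltfu_date <- as.Date(NA)
  censor_ga <- NA_integer_
  if (is.na(implaus_variant) && outcome != "miscarriage" &&
      runif(1) < cfg$ltfu_rate && delivery_ga - enroll_ga > 2L) {
    ltfu <- TRUE
    censor_ga <- enroll_ga + 1L +
      as.integer(floor(runif(1) * (delivery_ga - enroll_ga - 1L)))
    ltfu_date <- true_lmp + censor_ga
  }

  # documented GA evidence (possibly noisy); recall always recorded so
  # every emitted record is resolvable
  noise <- function() if (cfg$evidence_noise_days == 0) 0L else
    sample(-cfg$evidence_noise_days:cfg$evidence_noise_days, 1)
  us_ga_weeks <- NA_real_; us_date <- as.Date(NA)
  if (runif(1) < cfg$us_prob) {
    scan_ga <- as.integer(round(runif(1, 8 * 7, min(24 * 7, delivery_ga - 7))))
    us_date <- true_lmp + scan_ga
    us_ga_weeks <- round((scan_ga + noise()) / 7, 2)
  }
  lmp_date <- if (runif(1) < cfg$lmp_prob) true_lmp + noise() else as.Date(NA)
  fundal_height_cm <- if (runif(1) < 0.5)
    round(enroll_ga / 7 + noise() / 7, 1) else NA_real_
  recall_months <- as.integer(round(enroll_ga / DAYS_PER_MONTH))
  if (implaus_variant %in% "enroll") {
    # documented LMP equal to the enrollment date: documented GA 0 at
    # enrollment, an implausible record by construction
    lmp_date <- enrollment_date
    us_ga_weeks <- NA_real_; us_date <- as.Date(NA)
    fundal_height_cm <- NA_real_
    recall_months <- 0L
  } else if (implaus_variant %in% "delivery") {
    # the implausibility must live in the documentation itself: date this
    # record by an exact LMP so the recorded delivery GA is out of range
    # regardless of the noise processes
    lmp_date <- true_lmp
    us_ga_weeks <- NA_real_; us_date <- as.Date(NA)
    fundal_height_cm <- NA_real_
  }

  # emit visit records
  keep <- if (ltfu) visit_ga < censor_ga else rep(TRUE, length(visit_ga))
  post <- !pre & keep
  n_pro <- sum(post)
  n_retro <- if (retro) sum(pre & keep) else 0L
  visit_ga_date <- c(as.numeric(visit_dates[post]),
                     if (n_retro > 0) as.numeric(visit_dates[pre & keep]))
  visit_source <- c(rep("chart_prospective", n_pro),
                    rep("chart_retrospective", n_retro))

  list(
    woman_id = id,
    enrollment_date = as.numeric(enrollment_date),
    us_ga_weeks = us_ga_weeks, us_date = as.numeric(us_date),
    lmp_date = as.numeric(lmp_date),
    fundal_height_cm = fundal_height_cm, recall_months = recall_months,
    self_visits_enroll = reported,
    delivery_date = if (ltfu) NA_real_ else as.numeric(delivery_date),
    outcome = if (ltfu) "unknown" else outcome,
    ltfu = ltfu, ltfu_date = as.numeric(ltfu_date),
    age_years = round(min(49, max(15, rnorm(1, 27, 6))), 1),
    district = sample(c("District A", "District B"), 1, prob = c(0.45, 0.55)),
    literate = runif(1) < 0.55,
    wealth_q = sample(1:5, 1),
    ethnicity = sample(c("Amhara", "Oromo", "Other"), 1,
                       prob = c(0.913, 0.059, 0.028)),
    primiparous = runif(1) < 0.31,
    hist_stillbirth = runif(1) < 0.053,
    hist_preterm = runif(1) < 0.02,
    walk_minutes = round(min(360, stats::rgamma(1, shape = 1.5, scale = 45)), 1),
    visit_woman_id = rep(id, length(visit_source)),
    visit_ga_date = visit_ga_date,
    visit_source = visit_source,
    true_w1 = a[1], true_w2 = a[2], true_w3 = a[3], true_w4 = a[4],
    true_total_visits = length(visit_ga),
    true_pre_count = true_pre_count,
    true_enroll_ga_weeks = enroll_ga / 7,
    true_delivery_ga_weeks = delivery_ga / 7,
    miscarriage = outcome == "miscarriage",
    implausible = !is.na(implaus_variant),
    ltfu_truth = ltfu)
}
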