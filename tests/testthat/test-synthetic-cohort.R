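test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- sim_config(n_women = 150)
  a <- simulate_cohort(cfg, 101)
  b <- simulate_cohort(cfg, 101)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth$per_woman, b$truth$per_woman)
  c <- simulate_cohort(cfg, 102)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("appending women does not perturb existing ones", {
  a <- simulate_cohort(sim_config(n_women = 50), 7)
  b <- simulate_cohort(sim_config(n_women = 60), 7)
  expect_identical(a$cohort, b$cohort[1:50, ])
})

test_that("degenerate configs behave", {
  empty <- simulate_cohort(sim_config(n_women = 0), 1)
  expect_equal(nrow(empty$cohort), 0)
  expect_equal(nrow(empty$visits), 0)

  all_on <- sim_config(n_women = 120, window_attendance_probs = c(1, 1, 1, 1),
                       miscarriage_rate = 0, implausible_ga_rate = 0,
                       ltfu_rate = 0, selfreport_exact_prob = 1,
                       selfreport_error_spread = 0, frac_enroll_early = 1,
                       delivery_ga_range_weeks = c(37, 46),
                       us_prob = 0, lmp_prob = 1, evidence_noise_days = 0)
  sim <- simulate_cohort(all_on, 3)
  excl <- apply_exclusions(sim$cohort)
  flags <- assign_windows(select_subcohort(excl$analysis), sim$visits)
  cum <- cumulative_retention(flags)
  expect_equal(cum$proportion, rep(1, 4))
})

test_that("infeasible marginal/persistence combinations error at construction", {
  # p2 much larger than p1 with strong persistence forces q0 > 1
  expect_error(sim_config(window_attendance_probs = c(0.05, 0.9, 0.5, 0.3),
                          dropout_persistence = 1),
               class = "anccov_config")
  expect_error(sim_config(miscarriage_rate = 1.2), class = "anccov_config")
})

test_that("every emitted visit precedes delivery and implies non-negative GA", {
  sim <- simulate_cohort(sim_config(n_women = 400), 13)
  v <- dplyr::left_join(sim$visits, sim$cohort, by = "woman_id")
  delivered <- !is.na(v$delivery_date)
  expect_true(all(v$visit_date[delivered] < v$delivery_date[delivered]))
  tru <- sim$truth$per_woman
  lmp_true <- sim$cohort$enrollment_date -
    round(tru$true_enroll_ga_weeks[match(sim$cohort$woman_id, tru$woman_id)] * 7)
  ga <- as.integer(v$visit_date - lmp_true[match(v$woman_id, sim$cohort$woman_id)])
  expect_true(all(ga >= 0))
})

test_that("self-report error process hits its agreement and support contract", {
  expect_identical(apply_selfreport_error(0:5, exact_prob = 1, spread = 2), 0:5)
  set.seed(31)
  zeros <- apply_selfreport_error(rep(0L, 2000), exact_prob = 0, spread = 3)
  expect_true(all(zeros >= 0))
  set.seed(32)
  rep10k <- apply_selfreport_error(rep(2L, 10000), exact_prob = 0.5, spread = 1)
  agree <- mean(rep10k == 2L)
  expect_lt(abs(agree - 0.5), 0.015)
})

test_that("implied truth matches brute-force chain enumeration", {
  cfg <- sim_config(window_attendance_probs = c(0.7, 0.5, 0.45, 0.3),
                    dropout_persistence = 0.25)
  tru <- implied_truth(cfg)
  expect_equal(sum(tru$pattern_probs$prob), 1)
  # independent enumeration: walk every pattern with explicit conditionals
  p <- cfg$window_attendance_probs
  rho <- cfg$dropout_persistence
  q1 <- p[2:4] + rho * (1 - p[2:4])
  q0 <- (p[2:4] - p[1:3] * q1) / (1 - p[1:3])
  brute <- 0
  cum_brute <- numeric(4)
  marg <- numeric(4)
  for (bits in 0:15) {
    a <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0)
    pr <- if (a[1]) p[1] else 1 - p[1]
    for (k in 2:4) {
      q <- if (a[k - 1]) q1[k - 1] else q0[k - 1]
      pr <- pr * if (a[k]) q else 1 - q
    }
    if (any(a)) brute <- brute + pr
    for (k in 1:4) if (all(a[1:k])) cum_brute[k] <- cum_brute[k] + pr
    marg <- marg + pr * a
  }
  expect_equal(tru$p_any_visit, brute)
  expect_equal(tru$cumulative, cum_brute)
  expect_equal(marg, p) # transitions reproduce the requested marginals
  # independence special case
  ind <- implied_truth(sim_config(window_attendance_probs = p,
                                  dropout_persistence = 0))
  expect_equal(ind$p_any_visit, 1 - prod(1 - p))
  expect_equal(ind$cumulative, cumprod(p))
})

test_that("all-zero attendance gives zero expectations", {
  tru <- implied_truth(sim_config(window_attendance_probs = c(0, 0, 0, 0),
                                  dropout_persistence = 0))
  expect_equal(tru$p_any_visit, 0)
  expect_equal(tru$cumulative, rep(0, 4))
})

test_that("rates realised in a simulated cohort track the configured rates", {
  cfg <- sim_config(n_women = 4000)
  sim <- simulate_cohort(cfg, 55)
  tru <- sim$truth$per_woman
  expect_lt(abs(mean(tru$miscarriage) - cfg$miscarriage_rate), 0.012)
  expect_lt(abs(mean(tru$ltfu) - cfg$ltfu_rate * (1 - cfg$miscarriage_rate -
                                                    cfg$implausible_ga_rate)),
            0.02)
  excl <- apply_exclusions(sim$cohort)
  expect_equal(excl$tally$n_miscarriage, sum(tru$miscarriage))
  expect_equal(excl$tally$n_ltfu, sum(tru$ltfu))
  expect_equal(excl$tally$n_implausible_ga, sum(tru$implausible))
})
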