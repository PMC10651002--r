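paper_rows <- list(
  # x, n, pct, lo, hi — the published coverage / retention rows
  c(146, 150, 97.3, 93.1, 99.2),
  c(51, 150, 34.0, 26.9, 41.9),
  c(105, 121, 86.8, 79.5, 91.8),
  c(55, 88, 62.5, 52.0, 71.9),
  c(22, 74, 29.7, 20.5, 41.0),
  c(121, 150, 80.7, 73.6, 86.2),
  c(69, 150, 46.0, 38.2, 54.0),
  c(37, 150, 24.7, 18.4, 32.2),
  c(10, 131, 7.6, 4.0, 13.6))

test_that("Agresti-Coull reproduces every published table row at 1 decimal", {
  for (r in paper_rows) {
    est <- agresti_coull(r[1], r[2])
    expect_equal(round_half_up(100 * est$proportion, 1), r[3])
    expect_equal(round_half_up(100 * est$ci_low, 1), r[4])
    expect_equal(round_half_up(100 * est$ci_high, 1), r[5])
  }
})

test_that("Agresti-Coull clips, stays symmetric at 1/2, and contains x/n", {
  low <- agresti_coull(0, 10)
  expect_identical(low$ci_low, 0)
  hi <- agresti_coull(10, 10)
  expect_identical(hi$ci_high, 1)
  mid <- agresti_coull(75, 150)
  expect_equal(mid$ci_high - 0.5, 0.5 - mid$ci_low)
  # interval contains the raw proportion for all x, n <= 200 at level .95
  for (n in c(1:50, seq(60, 200, 10))) {
    est <- agresti_coull(0:n, n)
    expect_true(all(est$ci_low <= est$proportion + 1e-12 &
                      est$proportion <= est$ci_high + 1e-12))
  }
  expect_error(agresti_coull(1, 0), class = "anccov_undefined")
})

test_that("visit counts combine self-report and deduplicated prospective charts", {
  cohort <- make_cohort(2, self_visits_enroll = c(1L, 0L))
  visits <- make_visits(
    rep("A001", 4),
    as.Date("2019-03-01") + c(10, 10, 40, 80)) # one same-day duplicate
  counts <- assemble_visit_counts(cohort, visits)
  expect_equal(counts$n_prospective, c(3L, 0L))
  expect_equal(counts$n_total, c(4L, 0L))
  # chart_retrospective rows never enter totals
  visits2 <- dplyr::bind_rows(
    visits, make_visits("A002", "2019-02-01", "chart_retrospective"))
  expect_equal(assemble_visit_counts(cohort, visits2)$n_total, c(4L, 0L))
})

test_that("pre-enrollment prospective visits are reassigned or dropped with warning", {
  cohort <- make_cohort(2, self_visits_enroll = c(0L, 2L))
  visits <- make_visits(c("A001", "A002"), as.Date("2019-02-20"))
  expect_warning(counts <- assemble_visit_counts(cohort, visits),
                 "before enrollment")
  # self-report 0: reassigned to the pre-enrollment pool
  expect_equal(counts$n_total[counts$woman_id == "A001"], 1L)
  # self-report > 0: dropped to avoid double counting
  expect_equal(counts$n_total[counts$woman_id == "A002"], 2L)
})

test_that("simulated counts with exact self-report equal generator truth", {
  cfg <- sim_config(n_women = 400, selfreport_exact_prob = 1,
                    selfreport_error_spread = 0, ltfu_rate = 0,
                    miscarriage_rate = 0, implausible_ga_rate = 0)
  sim <- simulate_cohort(cfg, 21)
  counts <- assemble_visit_counts(sim$cohort, sim$visits)
  tru <- sim$truth$per_woman[match(counts$woman_id,
                                   sim$truth$per_woman$woman_id), ]
  expect_equal(counts$n_total, tru$true_total_visits)
})

test_that("coverage indicators are monotone, include the zero row, and resist reordering", {
  cfg <- sim_config(n_women = 300)
  sim <- simulate_cohort(cfg, 2)
  counts <- assemble_visit_counts(sim$cohort, sim$visits)
  cov <- coverage_indicators(counts)
  ge <- cov[startsWith(cov$indicator, ">="), ]
  expect_true(all(diff(ge$proportion) <= 0))
  zero <- cov[cov$indicator == "0 visits", ]
  expect_equal(zero$proportion, 1 - ge$proportion[1])
  shuffled <- counts[sample(nrow(counts)), ]
  expect_equal(coverage_indicators(shuffled), cov)
  expect_error(coverage_indicators(counts[0, ]), class = "anccov_undefined")
})

test_that("visit distribution sums to the denominator and 100 percent", {
  counts <- tibble::tibble(woman_id = letters[1:5],
                           n_total = c(0L, 3L, 3L, 2L, 5L))
  d <- visit_distribution(counts)
  expect_equal(sum(d$frequency), 5)
  expect_equal(sum(d$percent), 100)
  one <- visit_distribution(tibble::tibble(woman_id = "a", n_total = 2L))
  expect_equal(one$percent, 100)
})

test_that("median and IQR follow the sorted-order convention", {
  expect_equal(as.list(median_iqr(c(3, 3, 3))),
               list(median = 3, q1 = 3, q3 = 3))
  expect_equal(median_iqr(c(1, 2, 3, 4, 5))$median, 3)
  set.seed(8)
  x <- rpois(10000, 3)
  got <- median_iqr(x)
  s <- sort(x)
  expect_equal(got$q1, s[ceiling(0.25 * length(s))])
  expect_equal(got$q3, s[ceiling(0.75 * length(s))])
})

test_that("self-report agreement fractions partition the pairs", {
  all_eq <- tibble::tibble(reported = 1:4, chart = 1:4)
  expect_equal(selfreport_agreement(all_eq)$fraction, c(1, 0, 0))
  mixed <- tibble::tibble(reported = c(2, 1), chart = c(1, 2))
  got <- selfreport_agreement(mixed)
  expect_equal(got$fraction, c(0, 0.5, 0.5))
  expect_equal(sum(got$fraction), 1)
})
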