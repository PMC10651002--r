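test_that("visits map to half-open GA windows on integer days", {
  lmp <- as.Date("2019-01-01")
  cohort <- make_cohort(1, lmp_date = lmp,
                        enrollment_date = lmp + 60,
                        delivery_date = lmp + 273)
  excl <- apply_exclusions(cohort)
  # exactly 16.0 weeks (112 days) belongs to window 2; 28.0 to window 3;
  # 36.0 to window 4
  visits <- make_visits(rep("A001", 4), lmp + c(111, 112, 196, 252))
  flags <- assign_windows(excl$analysis, visits)
  expect_equal(unlist(flags[1, c("w1", "w2", "w3", "w4")],
                      use.names = FALSE),
               c(TRUE, TRUE, TRUE, TRUE))
  v2 <- make_visits("A001", lmp + 112)
  f2 <- assign_windows(excl$analysis, v2)
  expect_equal(unlist(f2[1, c("w1", "w2", "w3", "w4")], use.names = FALSE),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("pre-enrollment self-report sets only the window-1 flag", {
  cohort <- make_cohort(1, enrollment_date = as.Date("2019-01-01") + 63,
                        self_visits_enroll = 1L)
  excl <- apply_exclusions(cohort)
  flags <- assign_windows(excl$analysis, make_visits(character(0), as.Date(character(0))))
  expect_equal(unlist(flags[1, c("w1", "w2", "w3", "w4")], use.names = FALSE),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("a visit after delivery is a validation error naming the woman", {
  cohort <- make_cohort(1, delivery_date = as.Date("2019-09-20"))
  excl <- apply_exclusions(cohort)
  bad <- make_visits("A001", "2019-09-25")
  expect_error(assign_windows(excl$analysis, bad), "A001",
               class = "anccov_invalid")
})

test_that("window assignment matches generator truth exactly", {
  # early enrollment and exact evidence so pre-enrollment visits are all
  # window 1 and the self-report flag reconstruction is lossless
  cfg <- sim_config(n_women = 500, frac_enroll_early = 1,
                    selfreport_exact_prob = 1,
                    selfreport_error_spread = 0, ltfu_rate = 0,
                    miscarriage_rate = 0, implausible_ga_rate = 0,
                    us_prob = 0, lmp_prob = 1, evidence_noise_days = 0)
  sim <- simulate_cohort(cfg, 17)
  excl <- apply_exclusions(sim$cohort)
  flags <- assign_windows(excl$analysis, sim$visits)
  tru <- sim$truth$per_woman[match(flags$woman_id,
                                   sim$truth$per_woman$woman_id), ]
  expect_equal(flags$w1, tru$true_w1)
  expect_equal(flags$w2, tru$true_w2)
  expect_equal(flags$w3, tru$true_w3)
  expect_equal(flags$w4, tru$true_w4)
})

test_that("published retention counting examples hold", {
  # (F,T,F,T): in the ANC-2 denominator and numerator (returned via ANC 4)
  f <- make_flags("FTFT")
  seq2 <- sequential_retention(f, after = 2)
  expect_equal(c(seq2$numerator, seq2$denominator), c(1L, 1L))
  # hand enumeration: {TTFF, TFTF, TFFF} all delivering >= 36
  f3 <- make_flags(c("TTFF", "TFTF", "TFFF"))
  seq1 <- sequential_retention(f3, after = 1)
  expect_equal(seq1$proportion, 2 / 3)
  # (T,F,T,T): cumulative chain broken at window 2
  f4 <- make_flags("TFTT")
  cum <- cumulative_retention(f4)
  expect_equal(cum$numerator, c(1L, 0L, 0L, 0L))
})

test_that("the delivered-before-36-weeks exclusion applies exactly where footnoted", {
  f <- make_flags(c("TTTF", "TTTF"), delivery_ga_weeks = c(39, 34))
  seq3 <- sequential_retention(f, after = 3)
  expect_equal(seq3$denominator, 1L) # early delivery out of the ANC-3 denominator
  cum <- cumulative_retention(f)
  expect_equal(cum$denominator, c(2L, 2L, 2L, 1L))
  expect_error(sequential_retention(f, after = 4), class = "anccov_invalid")
})

test_that("retention agrees with the brute-force oracle on all patterns and at random", {
  pats <- apply(expand.grid(rep(list(c("T", "F")), 4)), 1, paste, collapse = "")
  exhaustive <- make_flags(c(pats, pats),
                           delivery_ga_weeks = rep(c(39, 34), each = 16))
  for (x in 1:3) {
    o <- oracle_sequential(exhaustive, x)
    got <- sequential_retention(exhaustive, after = x)
    expect_equal(c(got$numerator, got$denominator),
                 unname(c(o["num"], o["den"])))
  }
  for (k in 1:4) {
    o <- oracle_cumulative(exhaustive, k)
    got <- cumulative_retention(exhaustive, upto = k)
    expect_equal(c(got$numerator, got$denominator),
                 unname(c(o["num"], o["den"])))
  }
  set.seed(99)
  for (rep in 1:25) {
    f <- random_flags(40)
    for (x in 1:3) {
      o <- oracle_sequential(f, x)
      if (o["den"] == 0) next
      got <- sequential_retention(f, after = x)
      expect_equal(c(got$numerator, got$denominator),
                   unname(c(o["num"], o["den"])))
    }
    for (k in 1:4) {
      o <- oracle_cumulative(f, k)
      got <- cumulative_retention(f, upto = k)
      expect_equal(c(got$numerator, got$denominator),
                   unname(c(o["num"], o["den"])))
    }
  }
})

test_that("cumulative retention is non-increasing on the fixed denominator", {
  set.seed(4)
  f <- random_flags(200)
  cum <- cumulative_retention(f, upto = 1:3)
  expect_true(all(diff(cum$proportion) <= 0))
})

test_that("flow table counts all 16 patterns and marginalises correctly", {
  expect_equal(sum(flow_table(make_flags(character(0)))$count), 0)
  set.seed(12)
  f <- random_flags(300)
  ft <- flow_table(f)
  expect_equal(nrow(ft), 16)
  expect_equal(sum(ft$count), 300)
  m <- do.call(rbind, strsplit(ft$pattern, "")) == "T"
  expect_equal(colSums(m * ft$count),
               c(sum(f$w1), sum(f$w2), sum(f$w3), sum(f$w4)),
               ignore_attr = TRUE)
})
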