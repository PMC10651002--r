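---
title: "Estimating antenatal-care coverage and retention from a longitudinal pregnancy cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating antenatal-care coverage and retention from a longitudinal pregnancy cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anccov)
```

## The estimation problem

Antenatal-care (ANC) coverage — the proportion of pregnant women attending
at least 1, 4, or 8 ANC visits — is usually estimated from retrospective
self-reports, which suffer recall and social-desirability bias. A
longitudinal pregnancy cohort with prospective facility-chart abstraction
permits a less assumption-laden estimate: restrict to women enrolled early
in pregnancy (before 13 weeks gestation), count their subsequent visits
directly from charts, and add only the short-recall self-reported count of
visits before enrollment. This package implements that estimation pipeline
end to end, together with retention metrics over gestational-age visit
windows, a loss-to-follow-up (LTFU) scenario analysis, and a seeded
synthetic-cohort generator used to validate every estimator against known
truth.

## Gestational-age dating

All timing rests on one gestational-age (GA) anchor per pregnancy: a
reference date plus GA in **integer days** at that date. Weeks are derived
views; keeping days as the internal unit makes half-open window boundaries
(16 weeks = 112 days, 28 = 196, 36 = 252) exact integer comparisons with
no floating-point drift.

The anchor comes from a fixed evidence hierarchy: an ultrasound performed
before 16 weeks GA; otherwise the last menstrual period (LMP), accepted
against a later scan only when the two dating estimates disagree by at most
`discrepancy_limit_days`; otherwise LMP alone; otherwise fundal height at
1 cm per gestational week; otherwise maternal recall of months pregnant at
365.25/12 days per month. Three of these rules carry conventions rather
than universal constants, so they are configurable:

* `discrepancy_limit_days` (default **10 days**) — the "limited
  discrepancy" allowed between LMP and a second-trimester scan is a
  clinical-judgment quantity; 10 days is a conventional second-trimester
  redating cut and every run records the value used.
* the fundal-height rule (default **1 cm/week**) anchored at the
  measurement date.
* the recall conversion (default **365.25/12 days/month**).

A record whose only dating evidence is a post-16-week ultrasound with no
confirmable LMP, fundal height, or recall is *unresolvable*; the
eligibility screen routes such records to the implausible-GA bucket rather
than guessing.

## Eligibility and exclusion order

The analysis cohort excludes, in a fixed order: (1) miscarriages
(pregnancy losses before 28 weeks); (2) implausible documented GA —
enrollment GA ≤ 0 or ≥ 46 weeks, delivery GA < 28 or ≥ 46 weeks, boundaries
taken literally; (3) loss to follow-up. Fixing the precedence makes the
tally buckets disjoint and well-defined; whether LTFU should be counted
before or after the GA screen is not externally determined, and this order
is the one under which the buckets sum cleanly. Lost women are retained
separately because the sensitivity scenarios need their pre-censoring
visit history.

## Coverage

Per woman, the total visit count is the number of *distinct*
`chart_prospective` visit dates on or after enrollment (a visit is a day;
same-day duplicate rows collapse) plus the self-reported count of visits
before enrollment. Retrospective chart abstractions never enter totals —
they exist only to audit the self-reports. A prospective visit dated
before enrollment is a data error: it is reassigned to the pre-enrollment
pool only when the self-report is zero and dropped otherwise, because
double counting is the worse failure mode under the additive combination
rule.

Binomial proportions carry **Agresti-Coull** intervals: with
\(z = \Phi^{-1}((1+\text{level})/2)\) (the exact quantile, ≈ 1.959964, not
1.96), \(\tilde n = n + z^2\), \(\tilde p = (x + z^2/2)/\tilde n\), the
interval is \(\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}\), clipped
to \([0,1]\); the point estimate stays \(x/n\). Report tables round
percentages to one decimal, halves away from zero; internal values are
never rounded.

Quartiles of the visit-count distribution use the inverse-empirical-CDF
convention (`quantile` type 1) by default, which returns observed integer
counts and therefore matches integer reporting of an IQR such as "2–4";
the convention is a parameter because published tables rarely state
theirs.

## Retention

Each dated visit maps to one of four windows by GA at the visit date:
ANC 1 `[0, 16)`, ANC 2 `[16, 28)`, ANC 3 `[28, 36)`, ANC 4 `[36, ∞)`
weeks, half-open. Undated pre-enrollment self-reported visits set only the
window-1 flag: the subcohort enrolls before 13 weeks, so those visits
necessarily precede window 2.

* **Sequential retention after window X** (X = 1, 2, 3): among attendees
  of window X, the fraction attending *any* later window — skipping ANC 3
  and returning at ANC 4 still counts as retained after ANC 2.
* **Cumulative retention up to window k**: the fraction of the whole
  subcohort attending windows 1..k without a gap.

Women delivering before 36 weeks never had a window 4; they are excluded
from exactly two denominators — sequential retention after ANC 3 and
cumulative retention to ANC 4 — and nowhere else. No retention is defined
"after ANC 4"; the API refuses the request rather than returning a
degenerate value. Both definitions are verified in the test suite against
a brute-force per-woman enumeration over all 16 attendance patterns
crossed with delivery before/after 36 weeks.

## Loss-to-follow-up scenarios

Attrition is handled by deterministic bounding, not imputation. For
"at least one visit", lost women count as covered only if a visit was
recorded before censoring. For "four or more", a lost woman with \(v\)
visits at censoring counts fully if \(v \ge 4\) and otherwise contributes
\(f \cdot \hat P(\text{total} \ge 4 \mid \text{total} \ge v)\), the
empirical conditional among completers attenuated by \(f \in [0, 1]\)
(swept 0–90%). This conditional-on-visits-at-loss construction is the
most literal operationalisation of attenuating lost women's coverage
"based on the number of visits attended when they were lost"; when no
completer reaches \(v\) the contribution falls back to the overall
completer coverage, logged. The expected numerator keeps its exact
fractional value for the point estimate and is rounded half-up only for
the interval. The estimates are provably bracketed by the
never-attend/fully-covered extremes and monotone in \(f\), and with zero
lost women every scenario returns the primary estimate bit for bit.

## Group comparability

Baseline covariates are compared between enrollment groups with a Welch
t-test (continuous) and a chi-squared test without continuity correction
(categorical), replaced by Fisher's exact test whenever any expected cell
count is below 5 — the conventional switching rule, recorded per row,
since published tables name the tests but not the rule. A covariate with
zero variance is reported without a test rather than erroring.

## The synthetic-cohort generator

No public individual-level data exist for this design, so the generator
is a first-class, tested module that emulates the features the estimators
rely on:

* enrollment GA: a fraction `frac_enroll_early` (default 0.072) uniform in
  [5, 13) weeks, the rest uniform in [13, 36);
* delivery GA: truncated normal, mean 39.5, SD 1.5, support [28, 46)
  weeks; miscarriages (default 2.7%) below 28 weeks; a small fraction
  (default 1.4%) constructed with out-of-range *documented* GA to exercise
  the exclusion screen (their documentation is made exact so the
  implausibility survives the evidence-noise process);
* window attendance: a two-state first-order Markov chain over the four
  windows with prescribed marginals (default 0.81, 0.59, 0.49, 0.29) and a
  persistence parameter ρ: attendance probability given the previous
  window was attended is \(p_{k+1} + \rho(1 - p_{k+1})\), with the
  complementary branch solved from the marginal constraint and infeasible
  combinations rejected at construction. ρ = 0 recovers independence; the
  default ρ = 0.1 adds mild positive dependence, the minimal structure
  able to move sequential retention relative to the margins. Each
  attended window yields exactly one visit, placed uniformly (in days)
  within the window, after 4 weeks GA and strictly before delivery — a
  stylisation under which the total count equals the number of windows
  attended;
* self-report: the true pre-enrollment count passes through an error
  process (exact with probability 0.5 by default, otherwise a nonzero
  uniform error up to ±2, clipped at zero); a subset of women (default
  25%) also get retrospective chart rows so the agreement audit has
  paired data;
* LTFU (default 6.3% of otherwise-eligible women): censoring at a uniform
  GA between enrollment and delivery, visits after censoring suppressed
  and delivery fields blanked;
* covariates: generated independently of the visit process.

All randomness flows through per-woman substreams derived from one master
seed, so identical (config, seed) gives byte-identical tables and
appending a woman does not perturb the others. `implied_truth()` returns
the closed-form pattern distribution, window marginals, any-visit
probability and cumulative-retention probabilities of the chain (ignoring
delivery truncation), verified in tests against an independent exhaustive
enumeration of the 16 patterns.

What the generator does **not** emulate: covariate effects on attendance,
facility choice, seasonality, gestational-age measurement error correlated
with attendance, more than one visit per window, or dependence beyond
first order (unidentifiable from margins and retention summaries alone).
Passing recovery tests therefore show estimator correctness under the
stated data-generating process, not robustness to real-world structure
outside it.

## Validation design and problem sizes

The estimator-recovery check simulates 20,000 women under a configuration
where the closed-form truth is exact: all women enrolled early, delivery
support restricted to [37, 46) weeks so truncation cannot bias window-4
attendance, evidence noise and self-report error off, no
miscarriage/implausible/LTFU mass. Empirical window margins, any-visit
coverage and cumulative retention must fall within 3 Monte-Carlo standard
errors of `implied_truth()`. Interval calibration is checked with 10,000
binomial replicates at n = 150, p = 0.34 (coverage required in
[0.93, 0.97]); the retention definitions are checked against the
brute-force oracle on 1,000 random flag tables; interval containment of
x/n is checked exhaustively for all x at a grid of n up to 200. The
demonstration profile used by the analysis scripts simulates 2,303
pregnancies. These sizes keep each check's Monte-Carlo error well inside
the tolerance it asserts.

## Known limitations

* The self-report agreement audit conditions on women having
  retrospective chart data; if abstraction availability correlated with
  attendance in real data, the audit subset would not be representative.
* The scenario analysis restricts lost women to the early-enrollment
  subcohort by default (`scenario_scope = "subcohort"`); scaling to the
  full cohort is available but changes the denominator's meaning.
* Fundal-height and recall dating are crude; their records inherit the
  corresponding GA error, as in routine data.
* The pipeline treats records as pre-linked; no deduplication across
  facilities is attempted, and missing covariates are never imputed.
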