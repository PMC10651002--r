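#!/usr/bin/env Rscript

# Apply the eligibility screen, select the first-trimester subcohort, and
# estimate ANC coverage (>=1, >=4, >=8 visits) with Agresti-Coull 95% CIs,
# the visit-count distribution, the median/IQR, and the self-report
# agreement. Writes the stage tables under results/.

library(anccov)

cohort <- read_cohort("scratch/data/cohort.csv")
visits <- read_visits("scratch/data/visits.csv")

excl <- apply_exclusions(cohort)
cat("cohort flow:\n"); print(as.data.frame(excl$tally))

sub <- select_subcohort(excl$analysis, 13)
cat(sprintf("enrolled <13 weeks: %d of %d (%.1f%%)\n",
            nrow(sub), nrow(excl$analysis),
            100 * nrow(sub) / nrow(excl$analysis)))

counts <- assemble_visit_counts(sub, visits)
coverage <- coverage_indicators(counts, thresholds = c(1, 4, 8))
print(as.data.frame(coverage))

dir.create("results", showWarnings = FALSE)
readr::write_csv(excl$tally, "results/exclusions.csv")
readr::write_csv(coverage, "results/coverage.csv")
readr::write_csv(visit_distribution(counts), "results/distribution.csv")
readr::write_csv(median_iqr(counts), "results/median_iqr.csv")

# whole-cohort coverage for comparison with the subcohort
counts_all <- assemble_visit_counts(excl$analysis, visits)
readr::write_csv(coverage_indicators(counts_all, thresholds = c(1, 4, 8)),
                 "results/coverage_all.csv")

# self-report quality, where retrospective chart counts exist
pairs <- merge(
  data.frame(woman_id = cohort$woman_id, reported = cohort$self_visits_enroll),
  aggregate(visit_date ~ woman_id,
            data = visits[visits$source == "chart_retrospective", ],
            FUN = function(d) length(unique(d))),
  by = "woman_id")
names(pairs)[3] <- "chart"
agr <- selfreport_agreement(pairs)
cat("self-report vs chart agreement:\n"); print(as.data.frame(agr))
readr::write_csv(agr, "results/selfreport_agreement.csv")
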