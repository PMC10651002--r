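#!/usr/bin/env Rscript

# Loss-to-follow-up sensitivity: recompute coverage under deterministic
# scenarios where lost women attend less than women followed to delivery —
# never again after censoring (>=1 visit), or at 0% to 90% of the
# completers' conditional coverage (>=4 visits).

library(anccov)

cohort <- read_cohort("scratch/data/cohort.csv")
visits <- read_visits("scratch/data/visits.csv")

excl <- apply_exclusions(cohort)
sub <- select_subcohort(excl$analysis, 13)
completers <- assemble_visit_counts(sub, visits)
lost <- excl$ltfu[!is.na(excl$ltfu$ga_enroll_weeks) &
                    excl$ltfu$ga_enroll_weeks < 13, ]
lost_counts <- assemble_visit_counts(lost, visits)
cat(sprintf("completers: %d; lost to follow-up enrolled <13 weeks: %d\n",
            nrow(completers), nrow(lost_counts)))

specs <- rbind(
  data.frame(outcome = "any_visit", f = NA_real_),
  data.frame(outcome = "four_plus", f = seq(0, 0.9, by = 0.1)))
sens <- run_scenarios(completers, lost_counts, specs)
print(as.data.frame(sens))
readr::write_csv(sens, "results/sensitivity.csv")
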