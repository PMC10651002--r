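#!/usr/bin/env Rscript

# Assign dated visits to the four gestational-age windows (<16, 16-<28,
# 28-<36, >=36 weeks) and compute sequential and cumulative retention with
# the delivered-before-36-weeks denominator exclusions, plus the
# attendance-pattern flow table behind the alluvial plot.

library(anccov)

cohort <- read_cohort("scratch/data/cohort.csv")
visits <- read_visits("scratch/data/visits.csv")

excl <- apply_exclusions(cohort)
sub <- select_subcohort(excl$analysis, 13)
flags <- assign_windows(sub, visits)

margins <- colMeans(as.matrix(flags[, c("w1", "w2", "w3", "w4")]))
cat("per-window attendance among women enrolled <13 weeks:\n")
print(round(100 * margins, 1))

retention <- rbind(
  cbind(kind = "sequential", sequential_retention(flags)),
  cbind(kind = "cumulative", cumulative_retention(flags)))
print(as.data.frame(retention))

readr::write_csv(retention, "results/retention.csv")
readr::write_csv(flow_table(flags), "results/flow.csv")
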