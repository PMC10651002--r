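#!/usr/bin/env Rscript

# Generate the demonstration cohort: ~2300 pregnancies with the margins the
# downstream analyses expect (7% first-trimester enrollment, window
# attendance falling from ~81% to ~29%, ~2.7% miscarriage, ~6.3% loss to
# follow-up, self-reports agreeing with charts about half the time).
# Writes cohort.csv, visits.csv and truth.json under scratch/data/.

library(anccov)

seed <- 20181201 %% .Machine$integer.max
cfg <- sim_config() # the demonstration profile; n_women = 2303
sim <- simulate_cohort(cfg, seed)

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
write_cohort(sim$cohort, "scratch/data/cohort.csv")
write_visits(sim$visits, "scratch/data/visits.csv")
jsonlite::write_json(
  list(seed = seed,
       implied = sim$truth$implied[c("window_marginals", "p_any_visit",
                                     "cumulative")],
       n_women = cfg$n_women),
  "scratch/data/truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d pregnancies, %d visit records\n",
            nrow(sim$cohort), nrow(sim$visits)))
cat(sprintf("implied coverage of >=1 visit (untruncated): %.1f%%\n",
            100 * sim$truth$implied$p_any_visit))
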