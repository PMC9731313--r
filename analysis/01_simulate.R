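#!/usr/bin/env Rscript
# Build the stimulus paradigm and the synthetic cohort ground truth.
#
# Generates the 2,000-event alternating multifeature sequence (1,000
# standards, 5 x 200 deviants at 900 ms SOA, no more than two consecutive
# deviants of a type), validates it, and draws the ground-truth component
# amplitudes for the full 43-subject cohort at both timepoints. Writes the
# events table and ground truth under results/.

suppressMessages(library(mferp))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cat7 <- build_catalog()
events <- generate_sequence(cat7, seed = 20260925)
check <- check_sequence(events)
stopifnot(check$pass)
write_event_table(events, "results/events.tsv")
cat(sprintf("sequence: %d events, %d standards, max same-type run %d, %.0f min\n",
            nrow(events), sum(events$condition == "standard"),
            check$max_type_run, total_duration(events)))

cfg <- cohort_config(seed = 20260925)
cohort <- simulate_cohort(cfg)
write.csv(cohort$subjects, "results/subjects.csv", row.names = FALSE)
write.csv(cohort$truth, "results/ground_truth.csv", row.names = FALSE)
saveRDS(cfg, "scratch/cohort_config.rds")
cat(sprintf("cohort: %d subjects (%d CI, %d NH), %d ground-truth rows\n",
            nrow(cohort$subjects),
            sum(cohort$subjects$clinical_group == "CI"),
            sum(cohort$subjects$clinical_group == "NH"),
            nrow(cohort$truth)))
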