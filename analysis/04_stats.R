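#!/usr/bin/env Rscript
# Significance gates and staged mixed models on the quantified cohort.
#
# One-sample t-tests per cell gate each (deviant, component) response into
# the clinical-group models (significant with correct polarity in at least
# one CI and one NH cell) and into the singing models (significant in the
# pooled CI group at T1 or T2); gated-in responses are fitted with the
# staged group x age x time and singing x time mixed models.

suppressMessages(library(mferp))
res <- readRDS("scratch/pipeline_result.rds")

cat("group-comparison gates:\n")
print(res$gates[res$gates$included, c("deviant", "component")],
      row.names = FALSE)
cat("singing gates (pooled CI):\n")
print(res$singing_gate[res$singing_gate$included,
                       c("deviant", "component")], row.names = FALSE)

tabs <- report_tables(res)
write.csv(tabs$models, "results/model_estimates.csv", row.names = FALSE)
ok <- tabs$models[!is.na(tabs$models$p) & tabs$models$p < 0.05 &
                    tabs$models$Parameter != "(Intercept)", ]
cat(sprintf("fitted %d group and %d singing models; %d significant fixed effects\n",
            length(res$group_models), length(res$singing_models), nrow(ok)))
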