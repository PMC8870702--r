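#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study cohorts.
#
# Emulates the study design: a discovery cohort of 10 ACA / 10 ACC / 10 NAC
# tissue samples and an independent validation cohort of 22 ACA / 21 ACC,
# each measured in triplicate for 16 target miRNAs plus the RNU48 and
# cel-miR-39 controls. Validation samples are written with group UNKNOWN;
# their true diagnoses go to a separate truth table used only at scoring.
#
# Usage: Rscript analysis/01_simulate.R [seed]   (default seed 1)

suppressPackageStartupMessages(library(adrenomir))
seed <- as.integer(c(commandArgs(trailingOnly = TRUE), "1")[1L])
dir.create("results", showWarnings = FALSE)

spec <- default_synthetic_spec()
disc <- generate_cohort(spec, "discovery", seed = child_seed(seed, "disc"))
val <- generate_cohort(spec, "validation", seed = child_seed(seed, "val"))

write_ct_table(disc$table, "results/ct_discovery.csv")
write_ct_table(val$table, "results/ct_validation.csv")
write.csv(data.frame(sample_id = names(val$truth), group = val$truth),
          "results/validation_truth.csv", row.names = FALSE)

cat(sprintf("discovery: %d wells (%d unmeasurable), validation: %d wells (%d unmeasurable)\n",
            nrow(disc$table), sum(is.na(disc$table$ct)),
            nrow(val$table), sum(is.na(val$table$ct))))
cat("unmeasurable wells occur in the weakly expressed down-regulated assays:\n")
print(sort(table(disc$table$assay[is.na(disc$table$ct)]), decreasing = TRUE))
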