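#!/usr/bin/env Rscript
# Stage 6 — diagnostic performance of the validated models.
#
# Reveals the validation diagnoses and scores each model's final calls and
# vote fractions: sensitivity, specificity, AUC, NPV, PPV (ACC = positive
# "patient" class), written in the percentage layout of the study's
# performance table.
#
# Usage: Rscript analysis/06_evaluate.R   (after 05_validate.R)

suppressPackageStartupMessages(library(adrenomir))

truth_df <- read.csv("results/validation_truth.csv")
truth <- setNames(truth_df$group, truth_df$sample_id)
model_numbers <- c(9L, 16L, 17L)
models <- candidate_models()$model[model_numbers]

vote_results <- lapply(seq_along(models), function(i) {
  tab <- read.csv(sprintf("results/votes_model%d.csv", model_numbers[i]),
                  colClasses = c(sample_id = "character"))
  lapply(seq_len(nrow(tab)), function(r) {
    structure(list(sample_id = tab$sample_id[r],
                   votes = c(ACA = tab$n_aca[r], ACC = tab$n_acc[r]),
                   vote_fraction_acc = tab$fraction_acc[r],
                   final_call = tab$call[r]), class = "vote_result")
  })
})
names(vote_results) <- models

report <- evaluate_models(vote_results, truth)
write_report(report, "results/performance.csv")
cat("diagnostic performance (ACC positive):\n")
print(cbind(model_number = model_numbers,
            report[c("model", "sensitivity", "specificity", "auc", "npv",
                     "ppv", "indeterminate")]), row.names = FALSE)
cat("wrote results/performance.csv\n")
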