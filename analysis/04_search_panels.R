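#!/usr/bin/env Rscript
# Stage 4 — combinatorial panel search.
#
# Scores the 24 candidate 2-4-miRNA combinations by 1000-repetition
# stratified 90-10 learner-tester neural-network cross-validation, in both
# the three-class (ACA/ACC/NAC) and two-class (tumors only) settings, and
# selects combinations with at least 90% classification capability.
#
# Usage: Rscript analysis/04_search_panels.R [seed]

suppressPackageStartupMessages(library(adrenomir))
seed <- as.integer(c(commandArgs(trailingOnly = TRUE), "1")[1L])

em <- read_expr_matrix("results/expr_discovery.csv")
combos <- lapply(candidate_models()$model, parse_combo)

all_modes <- lapply(c("three_class", "two_class"), function(mode) {
  sc <- search_config(n_reps = 1000L, group_mode = mode,
                      seed = child_seed(seed, paste0("search_", mode)))
  found <- search_panels(em, sc, combos = combos)
  found$mode <- mode
  found
})
found <- do.call(rbind, all_modes)
write.csv(found[c("model", "mode", "size", "capability")],
          "results/search_capabilities.csv", row.names = FALSE)

for (mode in c("three_class", "two_class")) {
  sel <- select_models(found[found$mode == mode, ], 0.90)
  cat(sprintf("%s: %d of %d combinations reach 90%% capability\n",
              mode, nrow(sel), length(combos)))
  if (nrow(sel)) print(head(sel, 10L), row.names = FALSE)
}
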