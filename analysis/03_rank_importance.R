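#!/usr/bin/env Rscript
# Stage 3 — random-forest marker ranking.
#
# Orders the discovery-cohort miRNAs by mean decrease in OOB accuracy
# (500 trees, three-class labels). The ranking corroborates which markers
# carry the group signal; it does not feed the classifier.
#
# Usage: Rscript analysis/03_rank_importance.R [seed]

suppressPackageStartupMessages(library(adrenomir))
seed <- as.integer(c(commandArgs(trailingOnly = TRUE), "1")[1L])

em <- read_expr_matrix("results/expr_discovery.csv")
imp <- rank_importance(em, forest_params(n_trees = 500L,
                                         seed = child_seed(seed, "rank")))
write.csv(imp, "results/importance.csv", row.names = FALSE)
cat("top 5 markers by mean decrease in accuracy:\n")
print(imp[1:5, ], row.names = FALSE)
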