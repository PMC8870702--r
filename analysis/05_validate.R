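#!/usr/bin/env Rscript
# Stage 5 — ensemble classification of the validation cohort.
#
# Each unknown validation sample is classified independently for the three
# best candidate models: per iteration a stratified 90% subset of the
# labeled discovery ACA/ACC samples retrains the network, and the majority
# (>50%) of the iteration calls decides the final label. 2000 iterations
# per sample are used here; vote fractions at this size are stable to
# about +/- 1 percentage point.
#
# Usage: Rscript analysis/05_validate.R [seed]

suppressPackageStartupMessages(library(adrenomir))
seed <- as.integer(c(commandArgs(trailingOnly = TRUE), "1")[1L])

known <- read_expr_matrix("results/expr_discovery.csv")
unknowns <- read_expr_matrix("results/expr_validation.csv")
models <- candidate_models()$model[c(9L, 16L, 17L)]

for (i in seq_along(models)) {
  vc <- vote_config(n_iterations = 2000L,
                    seed = child_seed(seed, "vote"))
  votes <- classify_cohort(known, unknowns, parse_combo(models[i]),
                           vote = vc)
  tab <- vote_table(votes)
  path <- sprintf("results/votes_model%d.csv", c(9L, 16L, 17L)[i])
  write.csv(tab, path, row.names = FALSE)
  cat(sprintf("%s: %d/%d called ACC, %d indeterminate -> %s\n",
              models[i], sum(tab$call == "ACC"), nrow(tab),
              sum(tab$call == "INDETERMINATE"), path))
}
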