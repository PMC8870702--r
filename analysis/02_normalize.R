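#!/usr/bin/env Rscript
# Stage 2 — delta-Ct normalization.
#
# Triplicates are averaged, each target Ct is referenced to the geometric
# mean of the two control Cts (RNU48 intrinsic, cel-miR-39 spike-in), and
# expression is stored as -deltaCt so larger means more expressed. Any
# assay left with an unmeasurable summary in a cohort is omitted from that
# cohort's matrix — the study's rule for down-regulated miRNAs with no
# measurable Ct.
#
# Usage: Rscript analysis/02_normalize.R   (after 01_simulate.R)

suppressPackageStartupMessages(library(adrenomir))
cfg <- run_config()

for (cohort in c("discovery", "validation")) {
  tab <- read_ct_table(sprintf("results/ct_%s.csv", cohort), cfg)
  em <- normalize_ct_table(tab, cfg)
  write_expr_matrix(em, sprintf("results/expr_%s.csv", cohort))
  dropped <- setdiff(unique(tab$assay),
                     c(colnames(em$values), cfg$control_assays))
  cat(sprintf("%s: %d samples x %d assays kept; omitted: %s\n", cohort,
              nrow(em$values), ncol(em$values),
              if (length(dropped)) paste(dropped, collapse = ", ")
              else "none"))
}
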