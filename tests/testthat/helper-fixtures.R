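# Fixtures built in code: tiny Ct tables and reduced synthetic specs used
# across the test files.

# A minimal long-form Ct data.frame: `samples` named by group, `assays`
# target names, constant Ct per assay unless overridden.
make_ct_df <- function(samples = c(S1 = "ACA", S2 = "ACC", S3 = "NAC"),
                       assays = c("hsa-miR-195", "hsa-miR-503"),
                       n_rep = 3L, target_ct = 30, control_ct = c(25, 25)) {
  all_assays <- c(assays, DEFAULT_CONTROLS)
  ct_of <- c(stats::setNames(rep(target_ct, length.out = length(assays)),
                             assays),
             stats::setNames(control_ct, DEFAULT_CONTROLS))
  df <- expand.grid(sample_id = names(samples), assay = all_assays,
                    replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  df$group <- unname(samples[df$sample_id])
  df$ct <- unname(ct_of[df$assay])
  df[c("sample_id", "group", "assay", "replicate", "ct")]
}

# Noise-free two-assay spec: deterministic Cts, useful for exact checks.
zero_noise_spec <- function(effect_log2 = 0, aca_vs_nac_log2 = 0,
                            baseline = c(30, 32), censor_above = 38) {
  assays <- data.frame(
    name = c("hsa-miR-503", "hsa-miR-195", "RNU48", "cel-miR-39"),
    direction = c("up_in_ACC", "down_in_ACC", "control", "control"),
    baseline_ct = c(baseline, 24, 22), stringsAsFactors = FALSE)
  synthetic_spec(assays, effect_log2 = effect_log2,
                 aca_vs_nac_log2 = aca_vs_nac_log2, replicate_sd = 0,
                 biological_sd = 0, censor_above = censor_above)
}

# Small well-separated expression matrix for classifier tests: two features,
# `n` samples per class, class means +/- delta.
make_blobs <- function(n = 10L, delta = 3, sd = 0.5, seed = 42L,
                       classes = c("ACA", "ACC")) {
  set.seed(seed)
  k <- length(classes)
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rnorm(n, i * delta, sd), rnorm(n, -i * delta, sd))
  }))
  ids <- sprintf("S%02d", seq_len(n * k))
  dimnames(X) <- list(ids, c("f1", "f2"))
  groups <- stats::setNames(rep(classes, each = n), ids)
  expr_matrix(X, matrix(FALSE, nrow(X), ncol(X)), groups)
}

# Independent one-line normalization oracle used by the equivalence tests.
oracle_neg_delta_ct <- function(ct, c1, c2) -(ct - sqrt(c1 * c2))

# Independent AUC oracle: brute-force Mann-Whitney over all (pos, neg) pairs.
oracle_auc <- function(scores, truth, positive = "ACC") {
  pos <- scores[truth[names(scores)] == positive]
  neg <- scores[truth[names(scores)] != positive]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
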