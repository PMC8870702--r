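test_that("replicate aggregation follows the mean/median/missing rules", {
  df <- make_ct_df(samples = c(S1 = "ACA", S2 = "ACC"),
                   assays = "hsa-miR-503")
  idx <- df$sample_id == "S1" & df$assay == "hsa-miR-503"
  df$ct[idx] <- c(30.0, 30.2, 30.4)
  tab <- ct_table(df)

  agg <- aggregate_replicates(tab, "mean")
  expect_equal(agg$ct[agg$sample_id == "S1" & agg$assay == "hsa-miR-503"],
               30.2)

  # a single surviving replicate carries the summary
  df$ct[idx] <- c(31.0, NA, NA)
  agg <- aggregate_replicates(ct_table(df), "mean")
  expect_equal(agg$ct[agg$sample_id == "S1" & agg$assay == "hsa-miR-503"],
               31.0)

  # all replicates unmeasurable -> missing summary
  df$ct[idx] <- NA
  agg <- aggregate_replicates(ct_table(df), "mean")
  expect_true(is.na(agg$ct[agg$sample_id == "S1" &
                             agg$assay == "hsa-miR-503"]))

  df$ct[idx] <- c(10, 30, 31)
  agg <- aggregate_replicates(ct_table(df), "median")
  expect_equal(agg$ct[agg$sample_id == "S1" & agg$assay == "hsa-miR-503"],
               30)
})

test_that("delta-Ct against the combined controls matches hand computations", {
  mk <- function(target_ct, c1, c2) {
    df <- make_ct_df(samples = c(S1 = "ACA"), assays = "hsa-miR-503",
                     target_ct = target_ct, control_ct = c(c1, c2))
    normalize_delta_ct(aggregate_replicates(ct_table(df)))
  }
  # equal controls: geometric mean is the common value
  expect_equal(mk(28, 25, 25)$values[1L, 1L], -3.0)
  # target equals the reference
  expect_equal(mk(25, 25, 25)$values[1L, 1L], 0.0)
  # hand-computed: ref = sqrt(24 * 26), value = -(30 - ref) = -5.0200 (4 dp)
  expect_equal(round(mk(30, 24, 26)$values[1L, 1L], 4), -5.0200)
  expect_equal(mk(30, 24, 26)$values[1L, 1L], -(30 - sqrt(24 * 26)))
})

test_that("a sample with an unmeasurable control is a normalization error", {
  df <- make_ct_df(samples = c(S1 = "ACA", S2 = "ACC"),
                   assays = "hsa-miR-503")
  df$ct[df$sample_id == "S2" & df$assay == "RNU48"] <- NA
  expect_error(normalize_delta_ct(aggregate_replicates(ct_table(df))),
               "sample S2 has a missing control")
})

test_that("missing policies: omission drops the assay, censor_fill floors it", {
  df <- make_ct_df()
  df$ct[df$sample_id == "S1" & df$assay == "hsa-miR-195"] <- NA
  em <- normalize_delta_ct(aggregate_replicates(ct_table(df)))
  expect_true(any(em$mask))

  omitted <- apply_missing_policy(em, "omit_feature")
  expect_false("hsa-miR-195" %in% colnames(omitted$values))
  expect_true("hsa-miR-503" %in% colnames(omitted$values))
  expect_false(any(omitted$mask))

  filled <- apply_missing_policy(em, "censor_fill", ct_max = 40)
  # controls are 25/25 -> ref 25; detection floor = -(40 - 25) = -15
  expect_equal(filled$values["S1", "hsa-miR-195"], -15)
  expect_false(any(filled$mask))

  # a fully observed matrix is untouched by either policy
  em_full <- normalize_delta_ct(aggregate_replicates(ct_table(make_ct_df())))
  expect_identical(apply_missing_policy(em_full, "omit_feature"), em_full)
  expect_identical(apply_missing_policy(em_full, "censor_fill"), em_full)
})

test_that("normalization is invariant to a common shift of target and controls", {
  for (shift in c(-2, 1, 3.5)) {
    df1 <- make_ct_df(samples = c(S1 = "ACA"), assays = "hsa-miR-503",
                      target_ct = 30, control_ct = c(25, 25))
    df2 <- make_ct_df(samples = c(S1 = "ACA"), assays = "hsa-miR-503",
                      target_ct = 30 + shift, control_ct = c(25, 25) + shift)
    v1 <- normalize_delta_ct(aggregate_replicates(ct_table(df1)))$values
    v2 <- normalize_delta_ct(aggregate_replicates(ct_table(df2)))$values
    expect_equal(v2, v1, tolerance = 1e-12)
  }
})

test_that("expression is strictly decreasing in target Ct with fixed controls", {
  cts <- c(20, 24, 28, 32, 36)
  vals <- vapply(cts, function(ct) {
    df <- make_ct_df(samples = c(S1 = "ACA"), assays = "hsa-miR-503",
                     target_ct = ct, control_ct = c(24, 26))
    normalize_delta_ct(aggregate_replicates(ct_table(df)))$values[1L, 1L]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("normalized values equal the one-line oracle on random tables", {
  set.seed(101)
  for (rep in 1:5) {
    n_s <- 5L; n_a <- 5L
    samples <- sprintf("S%d", 1:n_s)
    assays <- sprintf("hsa-miR-%d", c(9, 195, 375, 497, 503))
    ct <- matrix(runif(n_s * n_a, 22, 34), n_s)
    c1 <- runif(n_s, 20, 26); c2 <- runif(n_s, 20, 26)
    df <- rbind(
      data.frame(sample_id = rep(samples, n_a), group = "ACA",
                 assay = rep(assays, each = n_s), replicate = 1L,
                 ct = as.vector(ct)),
      data.frame(sample_id = rep(samples, 2L), group = "ACA",
                 assay = rep(DEFAULT_CONTROLS, each = n_s), replicate = 1L,
                 ct = c(c1, c2)))
    em <- normalize_delta_ct(aggregate_replicates(ct_table(df)))
    expected <- oracle_neg_delta_ct(ct, c1, c2)
    dimnames(expected) <- list(samples, assays)
    expect_equal(em$values[samples, assays], expected, tolerance = 1e-12)
  }
})

test_that("expression matrices round-trip through CSV", {
  em <- normalize_ct_table(
    generate_cohort(default_synthetic_spec(), "discovery", 2L)$table,
    run_config(missing_policy = "censor_fill"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_expr_matrix(em, path)
  back <- read_expr_matrix(path)
  expect_equal(back$values, em$values, tolerance = 1e-12)
  expect_equal(back$mask, em$mask)
  expect_equal(back$groups, em$groups)
})

test_that("arithmetic-mean control summary is available as a config switch", {
  df <- make_ct_df(samples = c(S1 = "ACA"), assays = "hsa-miR-503",
                   target_ct = 30, control_ct = c(24, 26))
  agg <- aggregate_replicates(ct_table(df))
  geo <- normalize_delta_ct(agg, control_summary = "geometric")
  ari <- normalize_delta_ct(agg, control_summary = "arithmetic")
  expect_equal(ari$values[1L, 1L], -(30 - 25))
  expect_true(geo$values[1L, 1L] != ari$values[1L, 1L])
})
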