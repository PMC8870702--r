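test_that("combination enumeration counts match binomial arithmetic", {
  nine <- sprintf("hsa-miR-%d", c(9, 195, 210, 375, 497, 503, 508, 21, 7))
  expect_length(enumerate_combinations(nine, 2L, 4L),
                choose(9, 2) + choose(9, 3) + choose(9, 4))  # 246

  expect_length(enumerate_combinations(letters[1:3], 3L, 3L), 1L)

  sixteen <- sprintf("m%02d", 1:16)
  expect_length(enumerate_combinations(sixteen, 2L, 4L),
                choose(16, 2) + choose(16, 3) + choose(16, 4))  # 2500

  expect_error(enumerate_combinations(nine, 4L, 2L), "min_size > max_size")
  expect_error(enumerate_combinations(letters[1:3], 2L, 5L), "exceeds")

  # deterministic lexicographic order, sizes ascending
  cmb <- enumerate_combinations(c("b", "a", "c"), 2L, 3L)
  expect_identical(cmb, list(c("a", "b"), c("a", "c"), c("b", "c"),
                             c("a", "b", "c")))
})

test_that("combination labels use the natural miRNA order of the field", {
  expect_equal(combo_label(c("hsa-miR-503", "hsa-miR-9", "hsa-miR-195")),
               "hsa-miR-9 + hsa-miR-195 + hsa-miR-503")
  expect_equal(combo_label(c("hsa-miR-483-5p", "hsa-miR-483-3p")),
               "hsa-miR-483-3p + hsa-miR-483-5p")
  expect_equal(parse_combo("hsa-miR-503 + hsa-miR-9"),
               c("hsa-miR-9", "hsa-miR-503"))
  # every candidate model label survives a parse/format round trip
  for (label in candidate_models()$model) {
    expect_equal(combo_label(parse_combo(label)), label)
    expect_true(all(parse_combo(label) %in% validation_panel()))
  }
  expect_equal(nrow(candidate_models()), 24L)
})

test_that("cross-validation is deterministic and order-invariant", {
  em <- normalize_ct_table(
    generate_cohort(default_synthetic_spec(), "discovery", 4L)$table)
  combo <- c("hsa-miR-210", "hsa-miR-503")
  sc <- search_config(n_reps = 5L, seed = 9L)
  r1 <- cross_validate_combination(em, combo, sc)
  r2 <- cross_validate_combination(em, combo, sc)
  expect_identical(r1, r2)
  r3 <- cross_validate_combination(em, rev(combo), sc)
  expect_equal(r3$capability, r1$capability)
  expect_equal(r3$per_rep_accuracies, r1$per_rep_accuracies)
  expect_equal(r1$capability, mean(r1$per_rep_accuracies))
  expect_true(all(r1$per_rep_accuracies >= 0 & r1$per_rep_accuracies <= 1))
})

test_that("zero-effect data yields chance capability in two-class mode", {
  spec <- default_synthetic_spec()
  spec$effect_log2[] <- 0
  spec$aca_vs_nac_log2[] <- 0
  em <- normalize_ct_table(generate_cohort(spec, "discovery", 5L)$table,
                           run_config(missing_policy = "censor_fill"))
  sc <- search_config(n_reps = 500L, group_mode = "two_class", seed = 5L)
  cv <- cross_validate_combination(em, c("hsa-miR-210", "hsa-miR-503"), sc)
  expect_gt(cv$capability, 0.4)
  expect_lt(cv$capability, 0.6)
})

test_that("a near-separable combination scores almost perfect capability", {
  spec <- default_synthetic_spec()
  spec$effect_log2[] <- 4
  spec$biological_sd <- 0.25
  em <- normalize_ct_table(generate_cohort(spec, "discovery", 6L)$table,
                           run_config(missing_policy = "censor_fill"))
  sc <- search_config(n_reps = 200L, group_mode = "two_class", seed = 6L)
  combo <- c("hsa-miR-195", "hsa-miR-503")
  cv <- cross_validate_combination(em, combo, sc)
  expect_gte(cv$capability, 0.95)

  # adding a pure-noise feature barely moves a high capability
  spec2 <- spec
  spec2$effect_log2["hsa-miR-9"] <- 0
  em2 <- normalize_ct_table(generate_cohort(spec2, "discovery", 6L)$table,
                            run_config(missing_policy = "censor_fill"))
  cv_base <- cross_validate_combination(em2, combo, sc)
  cv_noise <- cross_validate_combination(em2, c(combo, "hsa-miR-9"), sc)
  expect_lt(abs(cv_noise$capability - cv_base$capability), 0.05)
})

test_that("both group modes run on the same matrix without code change", {
  em <- normalize_ct_table(
    generate_cohort(default_synthetic_spec(), "discovery", 7L)$table)
  for (mode in c("three_class", "two_class")) {
    sc <- search_config(n_reps = 10L, group_mode = mode, seed = 7L)
    cv <- cross_validate_combination(em, c("hsa-miR-210", "hsa-miR-503"), sc)
    expect_true(cv$capability >= 0 && cv$capability <= 1)
  }
})

test_that("group sizes below the split requirement raise a named error", {
  em <- normalize_ct_table(
    generate_cohort(default_synthetic_spec(), "discovery", 8L)$table)
  small <- subset_expr(em, samples = rownames(em$values)[-(1:5)])
  expect_error(
    cross_validate_combination(small, c("hsa-miR-210", "hsa-miR-503"),
                               search_config(n_reps = 2L)),
    "group ACA")
})

test_that("model selection applies the threshold with deterministic ties", {
  mk <- function(label, capability) {
    structure(list(combination = parse_combo(label), label = label,
                   capability = capability,
                   per_rep_accuracies = capability), class = "cv_result")
  }
  res <- list(mk("hsa-miR-9 + hsa-miR-503", 0.95),
              mk("hsa-miR-195 + hsa-miR-503", 0.89))
  sel <- select_models(res, 0.90)
  expect_equal(sel$model, "hsa-miR-9 + hsa-miR-503")

  expect_equal(nrow(select_models(res, 0.99)), 0L)

  tie <- list(mk("hsa-miR-9 + hsa-miR-503", 0.91),
              mk("hsa-miR-195 + hsa-miR-503", 0.91))
  sel <- select_models(tie, 0.90)
  expect_equal(sel$model, c("hsa-miR-195 + hsa-miR-503",
                            "hsa-miR-9 + hsa-miR-503"))
  expect_error(select_models(list(), 0.9), "no results")
})
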