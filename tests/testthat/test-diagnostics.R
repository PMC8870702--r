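test_that("confusion metrics match hand counts on the study-sized example", {
  # 22 true positives (2 missed), 21 true negatives (1 false positive)
  truth <- c(rep("ACC", 22L), rep("ACA", 21L))
  names(truth) <- sprintf("V%02d", seq_along(truth))
  calls <- truth
  calls[1:2] <- "ACA"   # false negatives
  calls[23L] <- "ACC"   # false positive
  cm <- confusion_from_calls(calls, truth)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(20L, 2L, 20L, 1L))
  expect_equal(round(100 * cm$sensitivity, 2), 90.91)
  expect_equal(round(100 * cm$specificity, 2), 95.24)
  expect_equal(cm$sensitivity, 20 / 22)
  expect_equal(cm$specificity, 20 / 21)
})

test_that("perfect and inverted classifiers hit the metric extremes", {
  truth <- c(A = "ACC", B = "ACC", C = "ACA", D = "ACA")
  cm <- confusion_from_calls(truth, truth)
  expect_equal(c(cm$sensitivity, cm$specificity, cm$ppv, cm$npv),
               rep(1, 4L))
  inverted <- ifelse(truth == "ACC", "ACA", "ACC")
  names(inverted) <- names(truth)
  cm <- confusion_from_calls(inverted, truth)
  expect_equal(c(cm$sensitivity, cm$specificity, cm$ppv, cm$npv),
               rep(0, 4L))
  # a degenerate call set leaves the undefined metric flagged, never 0
  all_aca <- setNames(rep("ACA", 4L), names(truth))
  cm <- confusion_from_calls(all_aca, truth)
  expect_true(is.na(cm$ppv))
  expect_equal(cm$npv, 0.5)
})

test_that("confusion metrics match brute-force counts on enumerated grids", {
  # every assignment of 4 samples to truth x call in {ACA, ACC}
  labs <- c("ACA", "ACC")
  ids <- paste0("s", 1:4)
  grid <- expand.grid(t1 = labs, t2 = labs, t3 = labs, t4 = labs,
                      c1 = labs, c2 = labs, c3 = labs, c4 = labs,
                      stringsAsFactors = FALSE)
  set.seed(1)
  for (i in sample(nrow(grid), 40L)) {
    truth <- setNames(unlist(grid[i, 1:4]), ids)
    calls <- setNames(unlist(grid[i, 5:8]), ids)
    cm <- confusion_from_calls(calls, truth)
    tp <- sum(calls == "ACC" & truth == "ACC")
    fp <- sum(calls == "ACC" & truth == "ACA")
    tn <- sum(calls == "ACA" & truth == "ACA")
    fn <- sum(calls == "ACA" & truth == "ACC")
    expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(tp, fp, tn, fn))
    if (tp + fn > 0L) expect_equal(cm$sensitivity, tp / (tp + fn))
    if (tn + fp > 0L) expect_equal(cm$specificity, tn / (tn + fp))
  }
})

test_that("swapping the positive class swaps the paired metrics", {
  truth <- setNames(rep(c("ACC", "ACA"), c(12L, 9L)), paste0("v", 1:21))
  set.seed(2)
  calls <- setNames(sample(c("ACA", "ACC"), 21L, replace = TRUE),
                    names(truth))
  a <- confusion_from_calls(calls, truth, positive = "ACC")
  b <- confusion_from_calls(calls, truth, positive = "ACA")
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$ppv, b$npv)
  expect_equal(a$npv, b$ppv)
})

test_that("indeterminate calls are bookkept outside the four cells", {
  truth <- c(A = "ACC", B = "ACC", C = "ACA", D = "ACA")
  calls <- c(A = "ACC", B = "INDETERMINATE", C = "ACA", D = "ACA")
  cm <- confusion_from_calls(calls, truth)
  expect_equal(cm$indeterminate, 1L)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 3L)
  expect_error(confusion_from_calls(c(Z = "ACC"), truth), "no truth label")
})

test_that("ROC/AUC match the frozen oracle values", {
  # spec example, confirmed by pair enumeration: (3 + 0.5 * 0) / 4 = 0.75
  scores <- c(p1 = 0.9, p2 = 0.8, n1 = 0.85, n2 = 0.1)
  truth <- c(p1 = "ACC", p2 = "ACC", n1 = "ACA", n2 = "ACA")
  roc <- roc_from_scores(scores, truth)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc, oracle_auc(scores, truth))

  # perfectly separated scores
  sep <- c(p1 = 0.9, p2 = 0.8, n1 = 0.3, n2 = 0.1)
  expect_equal(roc_from_scores(sep, truth)$auc, 1.0)
  # exchangeable scores: chance
  flat <- c(p1 = 0.5, p2 = 0.5, n1 = 0.5, n2 = 0.5)
  expect_equal(roc_from_scores(flat, truth)$auc, 0.5)
  expect_error(roc_from_scores(sep, setNames(rep("ACC", 4), names(sep))),
               "each class")
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 10L
    scores <- setNames(round(runif(n), 2), paste0("s", 1:n))
    truth <- setNames(sample(rep(c("ACC", "ACA"), n / 2)), names(scores))
    roc <- roc_from_scores(scores, truth)
    expect_true(all(diff(roc$tpr) >= 0))
    expect_true(all(diff(roc$fpr) >= 0))
    expect_equal(c(roc$tpr[1L], roc$fpr[1L]), c(0, 0))
    expect_equal(c(max(roc$tpr), max(roc$fpr)), c(1, 1))
    # trapezoid AUC equals brute-force Mann-Whitney
    expect_equal(roc$auc, oracle_auc(scores, truth), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- setNames(runif(20L), paste0("s", 1:20))
  truth <- setNames(sample(rep(c("ACC", "ACA"), 10L)), names(scores))
  ours <- roc_from_scores(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("ACA", "ACC"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("binary-call ROC reduces to (sensitivity + specificity) / 2", {
  set.seed(5)
  truth <- setNames(sample(rep(c("ACC", "ACA"), 8L)), paste0("s", 1:16))
  calls <- setNames(sample(c("ACA", "ACC"), 16L, replace = TRUE),
                    names(truth))
  scores <- ifelse(calls == "ACC", 1, 0)
  names(scores) <- names(calls)
  cm <- confusion_from_calls(calls, truth)
  roc <- roc_from_scores(scores, truth)
  expect_equal(roc$auc, (cm$sensitivity + cm$specificity) / 2)
})

test_that("model evaluation emits one row per model with vote bookkeeping", {
  mk_vote <- function(id, call, frac) {
    structure(list(sample_id = id,
                   votes = c(ACA = round(100 * (1 - frac)),
                             ACC = round(100 * frac)),
                   vote_fraction_acc = frac, final_call = call,
                   iteration_calls = NULL), class = "vote_result")
  }
  truth <- c(V1 = "ACC", V2 = "ACC", V3 = "ACA", V4 = "ACA")
  perfect <- list(mk_vote("V1", "ACC", 0.9), mk_vote("V2", "ACC", 0.8),
                  mk_vote("V3", "ACA", 0.2), mk_vote("V4", "ACA", 0.1))
  with_ind <- list(mk_vote("V1", "ACC", 0.9),
                   mk_vote("V2", "INDETERMINATE", 0.5),
                   mk_vote("V3", "ACA", 0.2), mk_vote("V4", "ACA", 0.1))
  report <- evaluate_models(list(m1 = perfect, m2 = with_ind), truth)
  expect_equal(nrow(report), 2L)
  expect_equal(report$sensitivity[1L], 1)
  expect_equal(report$specificity[1L], 1)
  expect_equal(report$auc[1L], 1)
  expect_equal(report$indeterminate, c(0L, 1L))
  expect_equal(report$sensitivity[2L], 1)  # V2 excluded from the cells
  expect_error(evaluate_models(list(), truth), "no models")
})
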