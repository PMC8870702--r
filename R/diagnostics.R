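#' Confusion matrix and diagnostic metrics from final calls
#'
#' Standard epidemiological convention with the malignant class (ACC, the
#' "patient" group) as positive: tp = called ACC and truly ACC, tn = called
#' ACA and truly ACA. Samples called `INDETERMINATE` are counted separately
#' and never enter the four cells. A metric whose denominator is zero is
#' returned as `NA` (flagged, never a silent 0).
#'
#' @param calls named character vector sample -> called group.
#' @param truth named character vector sample -> true group (ACA/ACC).
#' @param positive the positive class (default `"ACC"`).
#' @return list of class `confusion_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `indeterminate`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `positive_class`.
#' @export
confusion_from_calls <- function(calls, truth, positive = "ACC") {
  missing_truth <- setdiff(names(calls), names(truth))
  if (length(missing_truth) > 0L) {
    stop("no truth label for sample(s): ",
         paste(missing_truth, collapse = ", "), call. = FALSE)
  }
  tr <- truth[names(calls)]
  assert_group(tr, "truth")
  if (any(!tr %in% c("ACA", "ACC"))) {
    stop("truth labels must be ACA or ACC", call. = FALSE)
  }
  ind <- calls == "INDETERMINATE"
  cl <- calls[!ind]; tr <- tr[!ind]
  negative <- setdiff(c("ACA", "ACC"), positive)
  tp <- sum(cl == positive & tr == positive)
  fp <- sum(cl == positive & tr == negative)
  tn <- sum(cl == negative & tr == negative)
  fn <- sum(cl == negative & tr == positive)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 indeterminate = sum(ind),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 positive_class = positive),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "tp=%d fp=%d tn=%d fn=%d (indeterminate %d); sens %.2f%% spec %.2f%%\n",
    x$tp, x$fp, x$tn, x$fn, x$indeterminate,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps the decision threshold over every distinct score (call positive
#' when score >= t) and integrates by the trapezoidal rule. The resulting
#' AUC equals the Mann-Whitney statistic
#' P(score_pos > score_neg) + 1/2 P(equal).
#'
#' @param scores named numeric vector sample -> score (here: the ACC vote
#'   fraction).
#' @param truth named character vector sample -> true group.
#' @param positive positive class (default `"ACC"`).
#' @return list of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_from_scores <- function(scores, truth, positive = "ACC") {
  tr <- truth[names(scores)]
  if (anyNA(tr)) stop("missing truth label for a scored sample",
                      call. = FALSE)
  is_pos <- tr == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("need at least one sample of each class", call. = FALSE)
  }
  # thresholds from +Inf (call nothing) down through each distinct score
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!is_pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Evaluate a set of panel models against revealed diagnoses
#'
#' One row per model with the study report's columns: sensitivity,
#' specificity, AUC (on the vote fractions), NPV and PPV, plus the count of
#' indeterminate calls.
#'
#' @param vote_results named list: model label -> list of `vote_result`.
#' @param truth named character vector sample -> true group.
#' @param positive positive class.
#' @return data.frame with columns `model`, `sensitivity`, `specificity`,
#'   `auc`, `npv`, `ppv` (fractions in [0,1]) and `indeterminate`.
#' @export
evaluate_models <- function(vote_results, truth, positive = "ACC") {
  if (length(vote_results) == 0L) stop("no models to evaluate",
                                       call. = FALSE)
  rows <- lapply(names(vote_results), function(label) {
    vr <- vote_results[[label]]
    ids <- vapply(vr, `[[`, "", "sample_id")
    calls <- stats::setNames(vapply(vr, `[[`, "", "final_call"), ids)
    scores <- stats::setNames(vapply(vr, `[[`, 0, "vote_fraction_acc"), ids)
    cm <- confusion_from_calls(calls, truth, positive)
    roc <- roc_from_scores(scores, truth, positive)
    data.frame(model = label, sensitivity = cm$sensitivity,
               specificity = cm$specificity, auc = roc$auc,
               npv = cm$npv, ppv = cm$ppv,
               indeterminate = cm$indeterminate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the diagnostic-performance report CSV
#'
#' Columns `model, sensitivity, specificity, auc, npv, ppv` with the
#' percentage metrics rendered to two decimals (e.g. `90.91%`), plus the
#' indeterminate count when present.
#'
#' @param report the data.frame from [evaluate_models()] (or any data.frame
#'   with those fraction-valued columns).
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  if (!is.data.frame(report) || nrow(report) == 0L) {
    stop("report must be a non-empty data.frame", call. = FALSE)
  }
  out <- report
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f%%", 100 * x))
  for (col in intersect(c("sensitivity", "specificity", "auc", "npv",
                          "ppv"), names(out))) {
    out[[col]] <- pct(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
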