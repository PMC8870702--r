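#' Enumerate candidate miRNA combinations
#'
#' All subsets of the assay list with sizes in [min_size, max_size], each
#' returned as a sorted character vector, in deterministic lexicographic
#' order (sizes ascending, names sorted within size).
#'
#' @param assays character vector of assay names.
#' @param min_size,max_size inclusive subset size bounds.
#' @return list of character vectors (the combinations).
#' @export
enumerate_combinations <- function(assays, min_size = 2L, max_size = 4L) {
  if (min_size > max_size) stop("min_size > max_size", call. = FALSE)
  if (max_size > length(assays)) {
    stop("max_size exceeds the number of assays", call. = FALSE)
  }
  assays <- sort(unique(assays))
  out <- list()
  for (k in seq(min_size, max_size)) {
    cmb <- utils::combn(assays, k, simplify = FALSE)
    ord <- order(vapply(cmb, paste, "", collapse = "\r"))
    out <- c(out, cmb[ord])
  }
  out
}

#' Canonical natural ordering of miRNA assay names
#'
#' Orders `hsa-miR-N[-arm]` names by their numeric part (so `hsa-miR-9`
#' precedes `hsa-miR-195`), arms `3p` before `5p`; names that do not match
#' the pattern sort alphabetically after. Used as the canonical member
#' order of a combination, so results are invariant to input listing order.
#'
#' @param assays character vector of assay names.
#' @return the names in canonical order.
#' @export
mir_sort <- function(assays) {
  assays <- unique(assays)
  m <- regmatches(assays, regexec("^hsa-miR-([0-9]+)(-([0-9a-z]+))?$",
                                  assays))
  num <- vapply(m, function(x) if (length(x)) as.numeric(x[2L]) else Inf,
                numeric(1))
  arm <- vapply(m, function(x) if (length(x)) x[4L] else "", "")
  assays[order(num, arm, assays)]
}

#' Format a combination the way the study's model table prints it
#' @param combo character vector of assay names.
#' @return single string `"a + b + c"` (members in canonical order).
#' @export
combo_label <- function(combo) paste(mir_sort(combo), collapse = " + ")

#' Parse a `"a + b + c"` combination label back to assay names
#' @param label combination string.
#' @return character vector in canonical order.
#' @export
parse_combo <- function(label) mir_sort(trimws(strsplit(label, "+",
                                                        fixed = TRUE)[[1L]]))

# Draw a stratified learner/tester split: for each group, learners_per_group
# learner indices and testers_per_group tester indices, disjoint.
stratified_split <- function(group_idx, learners_per_group,
                             testers_per_group) {
  learn <- integer(0); test <- integer(0)
  for (idx in group_idx) {
    pick <- sample(idx, learners_per_group + testers_per_group)
    learn <- c(learn, pick[seq_len(learners_per_group)])
    test <- c(test, pick[learners_per_group + seq_len(testers_per_group)])
  }
  list(learn = learn, test = test)
}

#' Score one combination by repeated learner-tester cross-validation
#'
#' The study's discovery procedure: per repetition draw a stratified
#' 9-per-group learner set (and 1-per-group testers) from the discovery
#' cohort, train the neural network on the combination's features, classify
#' the held-out testers, and record the fraction correct. Both the split
#' and the network initialization are refreshed per repetition from child
#' seeds of the search seed. "Classification capability" is the mean
#' per-repetition tester accuracy.
#'
#' @param matrix discovery [expr_matrix()] (no masked entries among the
#'   combination's assays).
#' @param combo character vector of 2-4 assay names.
#' @param config a [search_config()].
#' @param nn an [nn_config()] (its seed is overridden per repetition).
#' @return list of class `cv_result`: `combination`, `label`, `capability`,
#'   `per_rep_accuracies`.
#' @export
cross_validate_combination <- function(matrix, combo,
                                       config = search_config(),
                                       nn = nn_config()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  combo <- mir_sort(combo)
  sub <- subset_expr(matrix, assays = combo)
  if (any(sub$mask)) {
    stop("combination has unmeasured values in the analysis set: ",
         combo_label(combo), call. = FALSE)
  }
  wanted <- if (config$group_mode == "three_class") c("ACA", "ACC", "NAC")
            else c("ACA", "ACC")
  g <- sub$groups
  need <- config$learners_per_group + config$testers_per_group
  group_idx <- lapply(wanted, function(w) which(g == w))
  sizes <- lengths(group_idx)
  if (any(sizes < need)) {
    stop(sprintf("group %s has %d samples; %d needed",
                 wanted[which(sizes < need)[1L]], min(sizes), need),
         call. = FALSE)
  }
  X <- sub$values
  n_test <- length(wanted) * config$testers_per_group
  n_learn <- length(wanted) * config$learners_per_group
  n_reps <- config$n_reps
  learn <- matrix(0L, n_reps, n_learn)
  test <- matrix(0L, n_reps, n_test)
  for (r in seq_len(n_reps)) {
    set.seed(child_seed(config$seed, "search_split", r))
    sp <- stratified_split(group_idx, config$learners_per_group,
                           config$testers_per_group)
    stopifnot(length(intersect(sp$learn, sp$test)) == 0L,
              length(c(sp$learn, sp$test)) == n_learn + n_test)
    learn[r, ] <- sort(sp$learn)  # canonical order, as train_nn would use
    test[r, ] <- sp$test
  }
  seeds <- vapply(seq_len(n_reps),
                  function(r) child_seed(config$seed, "search_init", r),
                  integer(1))
  pred <- nn_batch_predict(X, as.character(g), sort(wanted), learn, test,
                           seeds, nn)
  truth <- matrix(as.character(g)[t(test)], n_reps, n_test, byrow = TRUE)
  hits <- rowSums(pred == truth)
  acc <- hits / n_test
  capability <- if (config$accuracy_pooling == "per_rep") mean(acc)
                else sum(hits) / (n_test * n_reps)
  structure(list(combination = combo, label = combo_label(combo),
                 capability = capability, per_rep_accuracies = acc),
            class = "cv_result")
}

#' Run the combinatorial panel search
#'
#' Scores every enumerated combination (or a supplied candidate list) by
#' [cross_validate_combination()].
#'
#' @param matrix discovery [expr_matrix()] after the missing policy.
#' @param config a [search_config()].
#' @param nn an [nn_config()].
#' @param combos optional list of combinations (character vectors); by
#'   default all subsets of the matrix's assays in the configured size
#'   range.
#' @return data.frame with columns `model` (label), `size`, `capability`,
#'   plus attribute `cv_results` (the full list).
#' @export
search_panels <- function(matrix, config = search_config(),
                          nn = nn_config(), combos = NULL) {
  if (is.null(combos)) {
    combos <- enumerate_combinations(colnames(matrix$values),
                                     config$min_size, config$max_size)
  }
  results <- lapply(combos, function(cm)
    cross_validate_combination(matrix, cm, config, nn))
  df <- data.frame(
    model = vapply(results, `[[`, "", "label"),
    size = lengths(lapply(results, `[[`, "combination")),
    capability = vapply(results, `[[`, 0, "capability"),
    stringsAsFactors = FALSE)
  attr(df, "cv_results") <- results
  df
}

#' Select combinations meeting the capability threshold
#'
#' Keeps combinations whose capability reaches the threshold (study rule:
#' at least 90%), ordered by capability descending with ties broken by
#' label.
#'
#' @param results list of `cv_result` objects or the data.frame from
#'   [search_panels()].
#' @param threshold capability cutoff in (0, 1].
#' @return data.frame `model`, `capability` of the selected combinations
#'   (possibly empty).
#' @export
select_models <- function(results, threshold = 0.90) {
  if (is.data.frame(results)) {
    df <- results[c("model", "capability")]
  } else {
    if (length(results) == 0L) stop("no results supplied", call. = FALSE)
    df <- data.frame(
      model = vapply(results, `[[`, "", "label"),
      capability = vapply(results, `[[`, 0, "capability"),
      stringsAsFactors = FALSE)
  }
  sel <- df[df$capability >= threshold, ]
  sel <- sel[order(-sel$capability, sel$model), ]
  rownames(sel) <- NULL
  sel
}
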