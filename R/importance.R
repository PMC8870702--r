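#' Forest hyperparameters for the importance ranking
#'
#' @param n_trees number of trees (default 500).
#' @param max_features_per_split candidate features tried per split;
#'   `NULL` means the classification convention floor(sqrt(p)).
#' @param min_leaf minimum terminal-node size.
#' @param seed integer seed.
#' @return object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500L, max_features_per_split = NULL,
                          min_leaf = 1L, seed = 0L) {
  stopifnot(n_trees >= 1L, min_leaf >= 1L, seed >= 0)
  structure(list(n_trees = as.integer(n_trees),
                 max_features_per_split = max_features_per_split,
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Fit the random forest used for marker ranking
#'
#' Bagged CART trees with per-split random feature subsetting and
#' out-of-bag bookkeeping, via the randomForest engine. The forest is used
#' only to order markers by importance, never as the diagnostic classifier.
#'
#' @param X numeric matrix (samples x features), fully observed.
#' @param y class labels (>= 2 classes present).
#' @param params a [forest_params()].
#' @return a fitted `randomForest` object (with `keep.inbag = TRUE`).
#' @export
fit_forest <- function(X, y, params = forest_params()) {
  stopifnot(is.matrix(X), !anyNA(X))
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("labels contain a single class", call. = FALSE)
  if (length(y) != nrow(X)) stop("label/sample length mismatch",
                                 call. = FALSE)
  mtry <- params$max_features_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  stopifnot(mtry >= 1L, mtry <= ncol(X))
  set.seed(params$seed)
  randomForest::randomForest(
    x = X, y = y, ntree = params$n_trees, mtry = mtry,
    nodesize = params$min_leaf, importance = TRUE, keep.inbag = TRUE)
}

#' Mean-decrease-in-accuracy importance and rank order
#'
#' For each feature, the out-of-bag accuracy decrease after permuting that
#' feature's out-of-bag values, averaged over trees (the raw, unscaled
#' permutation importance). Ties in rank are broken by assay name.
#'
#' @param forest a forest from [fit_forest()].
#' @return data.frame with columns `assay`, `mean_decrease_accuracy`,
#'   `rank` (1 = most important), ordered by rank.
#' @export
permutation_importance <- function(forest) {
  imp <- randomForest::importance(forest, type = 1L, scale = FALSE)
  mda <- imp[, 1L]
  ord <- order(-mda, names(mda))
  out <- data.frame(assay = names(mda)[ord],
                    mean_decrease_accuracy = unname(mda[ord]),
                    rank = seq_along(mda),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank markers of an expression matrix by forest importance
#'
#' Convenience wrapper: fits the forest on the (fully observed) expression
#' matrix with its group labels and returns the permutation-importance
#' ranking. By default the three-class discovery labels are used.
#'
#' @param matrix an [expr_matrix()] with no masked entries.
#' @param params a [forest_params()].
#' @param groups optional subset of group labels to keep (default: all
#'   labeled groups present).
#' @return the [permutation_importance()] data.frame.
#' @export
rank_importance <- function(matrix, params = forest_params(),
                            groups = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (any(matrix$mask)) {
    stop("expression matrix has masked entries; apply a missing policy first",
         call. = FALSE)
  }
  g <- matrix$groups
  keep <- if (is.null(groups)) g != "UNKNOWN" else g %in% groups
  permutation_importance(
    fit_forest(matrix$values[keep, , drop = FALSE], g[keep], params))
}
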