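#' Resolve a vote tally into a final call
#'
#' The class receiving strictly more than `threshold` of all votes wins;
#' anything else — in particular an exact 50/50 tie at the default
#' threshold — is `INDETERMINATE`.
#'
#' @param votes named integer vector of per-class vote counts.
#' @param threshold strict winning fraction (default 0.5).
#' @return the winning class name or `"INDETERMINATE"`.
#' @export
majority_call <- function(votes, threshold = 0.5) {
  total <- sum(votes)
  winner <- names(votes)[which.max(votes)]
  if (votes[winner] / total > threshold) winner else "INDETERMINATE"
}

#' Classify one unknown sample by ensemble majority vote
#'
#' The study's validation procedure: the unknown sample is classified many
#' times (study value 10,000) by networks retrained per iteration — in the
#' default `subsample_90` mode each iteration draws a stratified 90%
#' learner subset of the labeled ACA/ACC samples and a fresh weight
#' initialization; in `full_refit` mode all knowns are used and only the
#' initialization varies. The final call is the class receiving strictly
#' more than `majority_threshold` of the votes, `INDETERMINATE` on an exact
#' tie.
#'
#' @param known labeled [expr_matrix()] (ACA/ACC samples are used).
#' @param unknown named numeric feature vector (assay -> expression) or a
#'   1-row matrix covering the combination's assays, fully observed.
#' @param combo character vector of assay names (the panel).
#' @param nn an [nn_config()] (its seed is overridden per iteration).
#' @param vote a [vote_config()].
#' @param sample_id identifier used in the result and in per-sample seed
#'   derivation.
#' @return list of class `vote_result`: `sample_id`, `votes` (named
#'   counts), `vote_fraction_acc`, `final_call`.
#' @export
classify_sample <- function(known, unknown, combo, nn = nn_config(),
                            vote = vote_config(), sample_id = "unknown") {
  stopifnot(inherits(known, "expr_matrix"))
  combo <- mir_sort(combo)
  sub <- subset_expr(known, assays = combo)
  keep <- sub$groups %in% c("ACA", "ACC")
  X <- sub$values[keep, , drop = FALSE]
  g <- sub$groups[keep]
  if (any(sub$mask[keep, ])) {
    stop("labeled samples have unmeasured values for the panel",
         call. = FALSE)
  }
  if (min(table(factor(g, c("ACA", "ACC")))) < 2L) {
    stop("need at least 2 labeled samples per class", call. = FALSE)
  }
  if (is.matrix(unknown)) unknown <- unknown[1L, ]
  if (!all(combo %in% names(unknown))) {
    stop("unknown sample lacks feature(s): ",
         paste(setdiff(combo, names(unknown)), collapse = ", "),
         call. = FALSE)
  }
  x <- unknown[combo]
  if (anyNA(x)) {
    stop(sprintf("sample %s has an unmeasured value for assay %s",
                 sample_id, paste(combo[is.na(x)], collapse = ", ")),
         call. = FALSE)
  }

  idx_by_class <- list(which(g == "ACA"), which(g == "ACC"))
  n_sub <- vapply(idx_by_class,
                  function(i) max(2L, as.integer(floor(0.9 * length(i)))),
                  integer(1))
  # per-sample seed stream: independent of other unknowns and of their order
  base_seed <- child_seed(vote$seed, paste0("vote_", sample_id))
  n_iter <- vote$n_iterations
  Xall <- rbind(X, matrix(x, nrow = 1L))
  n_learn <- if (vote$resample_mode == "subsample_90") sum(n_sub)
             else nrow(X)
  learn <- matrix(0L, n_iter, n_learn)
  for (it in seq_len(n_iter)) {
    if (vote$resample_mode == "subsample_90") {
      set.seed(child_seed(base_seed, "vote_subsample", it))
      learn[it, ] <- sort(c(sample(idx_by_class[[1L]], n_sub[1L]),
                            sample(idx_by_class[[2L]], n_sub[2L])))
    } else {
      learn[it, ] <- sort(c(idx_by_class[[1L]], idx_by_class[[2L]]))
    }
  }
  test <- matrix(nrow(Xall), n_iter, 1L)
  seeds <- vapply(seq_len(n_iter),
                  function(it) child_seed(base_seed, "vote_init", it),
                  integer(1))
  pred <- nn_batch_predict(Xall, c(as.character(g), NA), c("ACA", "ACC"),
                           learn, test, seeds, nn)
  iteration_calls <- pred[, 1L]
  votes <- c(ACA = sum(iteration_calls == "ACA"),
             ACC = sum(iteration_calls == "ACC"))
  structure(list(sample_id = sample_id, votes = votes,
                 vote_fraction_acc = unname(votes["ACC"] / n_iter),
                 final_call = majority_call(votes, vote$majority_threshold),
                 iteration_calls = iteration_calls),
            class = "vote_result")
}

#' Classify a cohort of unknown samples
#'
#' Applies [classify_sample()] independently to every row of the unknown
#' expression matrix; per-sample seeds are derived from the sample id, so
#' the order of unknowns cannot change any individual result.
#'
#' @param known labeled [expr_matrix()].
#' @param unknowns [expr_matrix()] of unknown samples.
#' @param combo character vector of assay names.
#' @param nn an [nn_config()].
#' @param vote a [vote_config()].
#' @return list of `vote_result`, one per unknown sample (possibly empty).
#' @export
classify_cohort <- function(known, unknowns, combo, nn = nn_config(),
                            vote = vote_config()) {
  stopifnot(inherits(unknowns, "expr_matrix"))
  combo <- mir_sort(combo)
  ids <- rownames(unknowns$values)
  sub <- subset_expr(unknowns, assays = combo)
  lapply(ids, function(s) {
    x <- sub$values[s, ]
    x[sub$mask[s, ]] <- NA_real_
    classify_sample(known, x, combo, nn, vote, sample_id = s)
  })
}

#' Tabulate vote results
#' @param results list of `vote_result`.
#' @return data.frame `sample_id`, `n_acc`, `n_aca`, `fraction_acc`, `call`.
#' @export
vote_table <- function(results) {
  data.frame(
    sample_id = vapply(results, `[[`, "", "sample_id"),
    n_acc = vapply(results, function(r) unname(r$votes["ACC"]), integer(1)),
    n_aca = vapply(results, function(r) unname(r$votes["ACA"]), integer(1)),
    fraction_acc = vapply(results, `[[`, 0, "vote_fraction_acc"),
    call = vapply(results, `[[`, "", "final_call"),
    stringsAsFactors = FALSE)
}
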