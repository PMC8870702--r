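#' The 24 candidate miRNA combination models
#'
#' The combinations of 2-4 miRNAs (drawn from the 9-miRNA refined
#' validation panel) that the discovery search put forward for validation,
#' numbered 1-24. Models 9, 16 and 17 are the three that achieved both
#' sensitivity and specificity above 90% in the original validation.
#'
#' @return data.frame with columns `model_number` and `model` (the
#'   `"a + b + c"` label).
#' @export
candidate_models <- function() {
  labels <- c(
    "hsa-miR-9 + hsa-miR-375",
    "hsa-miR-9 + hsa-miR-503",
    "hsa-miR-375 + hsa-miR-503",
    "hsa-miR-210 + hsa-miR-503",
    "hsa-miR-375 + hsa-miR-497",
    "hsa-miR-483-3p + hsa-miR-503",
    "hsa-miR-503 + hsa-miR-508",
    "hsa-miR-195 + hsa-miR-503 + hsa-miR-508",
    "hsa-miR-195 + hsa-miR-210 + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-195 + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-210 + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-375 + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-483-3p + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-497 + hsa-miR-503",
    "hsa-miR-195 + hsa-miR-375 + hsa-miR-497",
    "hsa-miR-210 + hsa-miR-375 + hsa-miR-503",
    "hsa-miR-210 + hsa-miR-483-5p + hsa-miR-503",
    "hsa-miR-375 + hsa-miR-503 + hsa-miR-508",
    "hsa-miR-375 + hsa-miR-483-3p + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-195 + hsa-miR-375 + hsa-miR-503",
    "hsa-miR-9 + hsa-miR-210 + hsa-miR-483-5p + hsa-miR-503",
    "hsa-miR-210 + hsa-miR-375 + hsa-miR-503 + hsa-miR-508",
    "hsa-miR-375 + hsa-miR-483-5p + hsa-miR-503 + hsa-miR-508",
    "hsa-miR-375 + hsa-miR-497 + hsa-miR-503 + hsa-miR-508")
  data.frame(model_number = seq_along(labels), model = labels,
             stringsAsFactors = FALSE)
}

#' The refined 9-miRNA validation panel
#'
#' The subset of targets re-measured on the validation cohort; every
#' candidate model draws its members from this set.
#'
#' @return character vector of 9 assay names.
#' @export
validation_panel <- function() {
  c("hsa-miR-9", "hsa-miR-195", "hsa-miR-210", "hsa-miR-375",
    "hsa-miR-483-3p", "hsa-miR-483-5p", "hsa-miR-497", "hsa-miR-503",
    "hsa-miR-508")
}

#' Run the full pipeline on synthetic cohorts
#'
#' Generates discovery and validation cohorts, normalizes both, scores the
#' requested panel models on the discovery cohort, classifies the
#' validation samples by ensemble vote, and evaluates the final calls
#' against the withheld truth. The single entry point used by the analysis
#' drivers and the acceptance checks.
#'
#' @param spec a [synthetic_spec()].
#' @param models character vector of model labels (default: the three best
#'   candidates).
#' @param config a [run_config()]; its `search`, `nn` and `vote` components
#'   drive the corresponding stages.
#' @param seed master seed overriding `config$seed`.
#' @param run_search if FALSE, skip discovery cross-validation scoring.
#' @return list: `discovery`, `validation` (expr matrices), `truth`,
#'   `search` (data.frame or NULL), `votes` (model -> vote_result list),
#'   `report` (evaluation data.frame).
#' @export
run_pipeline <- function(spec = default_synthetic_spec(),
                         models = candidate_models()$model[c(9L, 16L, 17L)],
                         config = run_config(), seed = config$seed,
                         run_search = TRUE) {
  disc <- generate_cohort(spec, "discovery", seed = child_seed(seed, "disc"))
  val <- generate_cohort(spec, "validation", seed = child_seed(seed, "val"))
  em_disc <- normalize_ct_table(disc$table, config)
  em_val <- normalize_ct_table(val$table, config)

  combos <- lapply(models, parse_combo)
  available <- colnames(em_disc$values)
  usable <- vapply(combos, function(cm) all(cm %in% available), logical(1))
  if (!all(usable)) {
    stop("model(s) reference omitted assay(s): ",
         paste(models[!usable], collapse = "; "), call. = FALSE)
  }

  search <- NULL
  if (run_search) {
    sc <- config$search
    sc$seed <- child_seed(seed, "search")
    search <- search_panels(em_disc, sc, config$nn, combos = combos)
  }

  vc <- config$vote
  vc$seed <- child_seed(seed, "vote")
  votes <- lapply(combos, function(cm) {
    ok <- rownames(em_val$values)
    classify_cohort(em_disc, subset_expr(em_val, samples = ok), cm,
                    config$nn, vc)
  })
  names(votes) <- vapply(combos, combo_label, "")
  report <- evaluate_models(votes, val$truth)
  list(discovery = em_disc, validation = em_val, truth = val$truth,
       search = search, votes = votes, report = report)
}
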