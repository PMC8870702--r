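#' @useDynLib adrenomir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd predict aggregate
#' @importFrom utils read.csv write.csv combn
NULL

#' Tissue group labels
#'
#' The three histological classes plus the placeholder carried by
#' validation-cohort samples whose diagnosis is withheld from the
#' classifier: `ACA` (adrenocortical adenoma, benign), `ACC`
#' (adrenocortical carcinoma, malignant), `NAC` (normal adrenal cortex)
#' and `UNKNOWN`.
#'
#' @export
GROUP_LEVELS <- c("ACA", "ACC", "NAC", "UNKNOWN")

#' Default control assay names
#'
#' `RNU48` is the intrinsic (housekeeping) control, `cel-miR-39` the
#' exogenous spike-in added before RNA isolation.
#'
#' @export
DEFAULT_CONTROLS <- c("RNU48", "cel-miR-39")

assert_group <- function(x, where = "group") {
  bad <- setdiff(unique(as.character(x)), GROUP_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s label(s): %s (allowed: %s)",
                 where, paste(bad, collapse = ", "),
                 paste(GROUP_LEVELS, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single master seed fans out to per-stage (and per-repetition) seeds so
#' that each stage is independently reproducible. The derivation hashes the
#' stage name with the master seed and an optional index; the result is a
#' valid 32-bit seed.
#'
#' @param master integer master seed (>= 0).
#' @param stage character scalar naming the stage (e.g. "search").
#' @param index optional nonnegative integer (repetition / sample index).
#' @return an integer in [0, 2^31 - 2].
#' @export
child_seed <- function(master, stage, index = 0L) {
  stopifnot(length(master) == 1L, master >= 0, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # Linear congruential mix; modulus 2^31 - 1 keeps the value a legal seed.
  val <- (as.double(master) * 48271 + h * 16807 + as.double(index) * 69621) %%
    2147483647
  as.integer(val)
}

#' Neural-network configuration
#'
#' Settings for the single-hidden-layer classifier used by the panel search
#' and the ensemble vote. Defaults follow the conventions of small
#' feed-forward classifiers on standardized inputs: a narrow hidden layer,
#' mild weight decay, and a fixed full-batch epoch budget (no early
#' stopping) so training is deterministic given the seed.
#'
#' @param hidden_units hidden layer width (>= 1).
#' @param weight_decay L2 penalty on connection weights (biases exempt).
#' @param max_epochs number of full-batch gradient steps.
#' @param learning_rate step size for gradient descent.
#' @param init_scale weights initialized Uniform(-init_scale, init_scale).
#' @param seed integer seed for weight initialization.
#' @return an object of class `nn_config`.
#' @export
nn_config <- function(hidden_units = 3L, weight_decay = 0.01,
                      max_epochs = 200L, learning_rate = 0.2,
                      init_scale = 0.5, seed = 0L) {
  stopifnot(hidden_units >= 1L, max_epochs >= 1L, weight_decay >= 0,
            learning_rate > 0, init_scale > 0, seed >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "nn_config")
}

#' Panel-search configuration
#'
#' Controls the repeated stratified learner-tester cross-validation: per
#' repetition 9 learners and 1 tester are drawn per group (the 90-10 split
#' of 10-sample groups), the network is retrained from a fresh child seed,
#' and the held-out testers are classified. Combinations whose mean tester
#' accuracy ("classification capability") reaches `selection_threshold`
#' are selected.
#'
#' @param n_reps repetitions of the random split (study value 1000).
#' @param learners_per_group,testers_per_group stratified split sizes.
#' @param selection_threshold capability needed for selection (study: 0.90).
#' @param group_mode `"three_class"` (ACA/ACC/NAC) or `"two_class"`
#'   (ACA/ACC only); both run on the same expression matrix.
#' @param min_size,max_size combination sizes enumerated (study: 2-4).
#' @param accuracy_pooling `"per_rep"` (mean of per-repetition tester
#'   accuracies, default) or `"pooled"` (accuracy over all tester samples of
#'   all repetitions); identical when `testers_per_group == 1`.
#' @param seed master seed for the search stage.
#' @return an object of class `search_config`.
#' @export
search_config <- function(n_reps = 1000L, learners_per_group = 9L,
                          testers_per_group = 1L,
                          selection_threshold = 0.90,
                          group_mode = c("three_class", "two_class"),
                          min_size = 2L, max_size = 4L,
                          accuracy_pooling = c("per_rep", "pooled"),
                          seed = 0L) {
  group_mode <- match.arg(group_mode)
  accuracy_pooling <- match.arg(accuracy_pooling)
  stopifnot(n_reps >= 1L, learners_per_group >= 1L, testers_per_group >= 1L,
            selection_threshold > 0, selection_threshold <= 1,
            min_size >= 1L, max_size >= min_size, seed >= 0)
  structure(list(n_reps = as.integer(n_reps),
                 learners_per_group = as.integer(learners_per_group),
                 testers_per_group = as.integer(testers_per_group),
                 selection_threshold = selection_threshold,
                 group_mode = group_mode,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 accuracy_pooling = accuracy_pooling,
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Majority-vote configuration
#'
#' Settings for the ensemble classification of unknown samples: each sample
#' is classified `n_iterations` times (study value 10,000) and the final
#' call is the class receiving strictly more than `majority_threshold` of
#' the votes; an exact tie is `INDETERMINATE`.
#'
#' @param n_iterations ensemble size per unknown sample.
#' @param majority_threshold strict vote fraction needed for a call
#'   (default 0.5, i.e. > 50%).
#' @param resample_mode `"subsample_90"` (default): each iteration retrains
#'   on a stratified 90% subset of the known samples with a fresh
#'   initialization; `"full_refit"`: all knowns, initialization-only
#'   randomness.
#' @param seed master seed for the validation stage.
#' @return an object of class `vote_config`.
#' @export
vote_config <- function(n_iterations = 10000L, majority_threshold = 0.5,
                        resample_mode = c("subsample_90", "full_refit"),
                        seed = 0L) {
  resample_mode <- match.arg(resample_mode)
  stopifnot(n_iterations >= 1L, majority_threshold >= 0,
            majority_threshold < 1, seed >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 majority_threshold = majority_threshold,
                 resample_mode = resample_mode,
                 seed = as.integer(seed)),
            class = "vote_config")
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings with the shared plumbing: the control
#' assay names, the qPCR cycle ceiling, the triplicate aggregation policy,
#' the missing-measurement policy and the master seed from which all stage
#' seeds are derived via [child_seed()].
#'
#' @param control_assays names of the two control assays.
#' @param ct_max maximum valid Ct (cycles); the instrument cycle ceiling.
#' @param replicate_policy `"mean"` (default) or `"median"` across wells.
#' @param missing_policy `"omit_feature"` (drop any assay with an
#'   unmeasurable sample, the study's rule) or `"censor_fill"` (impute at
#'   the detection floor).
#' @param control_summary `"geometric"` (default; geometric mean of the two
#'   control Cts) or `"arithmetic"`.
#' @param nn,search,vote stage configurations.
#' @param seed master seed (>= 0).
#' @return an object of class `run_config`.
#' @export
run_config <- function(control_assays = DEFAULT_CONTROLS, ct_max = 40,
                       replicate_policy = c("mean", "median"),
                       missing_policy = c("omit_feature", "censor_fill"),
                       control_summary = c("geometric", "arithmetic"),
                       nn = nn_config(), search = search_config(),
                       vote = vote_config(), seed = 0L) {
  replicate_policy <- match.arg(replicate_policy)
  missing_policy <- match.arg(missing_policy)
  control_summary <- match.arg(control_summary)
  stopifnot(length(control_assays) == 2L, ct_max > 0, seed >= 0,
            inherits(nn, "nn_config"), inherits(search, "search_config"),
            inherits(vote, "vote_config"))
  structure(list(control_assays = control_assays, ct_max = ct_max,
                 replicate_policy = replicate_policy,
                 missing_policy = missing_policy,
                 control_summary = control_summary,
                 nn = nn, search = search, vote = vote,
                 seed = as.integer(seed)),
            class = "run_config")
}
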