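#' Synthetic study specification
#'
#' Parameters of the Ct-table generator that emulates the study design:
#' 16 literature-selected target miRNAs plus the two controls, measured in
#' triplicate on a discovery cohort of 10 ACA / 10 ACC / 10 NAC samples and
#' a validation cohort of 22 ACA / 21 ACC samples whose labels are withheld.
#'
#' Group effects act on the Ct scale under the qPCR doubling assumption
#' (1 cycle = 1 log2 expression unit): an `up_in_ACC` assay with
#' `effect_log2 = 2` has ACC mean Ct two cycles below ACA. `aca_vs_nac_log2`
#' shifts the tumor groups away from normal cortex along the same direction.
#' Replicates exceeding `censor_above` cycles are reported unmeasurable,
#' the way instruments report "Undetermined" wells.
#'
#' @param assays data.frame with columns `name`, `direction`
#'   (`up_in_ACC` / `down_in_ACC` / `control`) and `baseline_ct` (cycles;
#'   the NAC latent mean).
#' @param effect_log2 named or scalar log2 shift of ACC relative to ACA
#'   (sign taken from `direction`).
#' @param aca_vs_nac_log2 named or scalar log2 shift of ACA relative to NAC
#'   along the assay's direction.
#' @param replicate_sd technical (well-to-well) noise sd, cycles.
#' @param biological_sd between-sample noise sd, cycles; control assays get
#'   one third of it so normalization is genuinely exercised.
#' @param n_per_group named counts for the discovery cohort.
#' @param n_validation named counts for the validation cohort.
#' @param n_replicates wells per (sample, assay).
#' @param censor_above Ct ceiling above which a well is unmeasurable.
#' @param seed default seed used when [generate_cohort()] is not given one.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(assays, effect_log2 = 2.0, aca_vs_nac_log2 = 1.0,
                           replicate_sd = 0.25, biological_sd = 0.75,
                           n_per_group = c(ACA = 10L, ACC = 10L, NAC = 10L),
                           n_validation = c(ACA = 22L, ACC = 21L),
                           n_replicates = 3L, censor_above = 38,
                           seed = 0L) {
  stopifnot(is.data.frame(assays),
            all(c("name", "direction", "baseline_ct") %in% names(assays)),
            all(assays$direction %in% c("up_in_ACC", "down_in_ACC",
                                        "control")),
            !anyDuplicated(assays$name),
            replicate_sd >= 0, biological_sd >= 0, n_replicates >= 1L,
            all(n_per_group >= 0L), all(n_validation >= 0L))
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, nrow(assays)), assays$name)
    }
    stopifnot(all(assays$name %in% names(x)))
    x[assays$name]
  }
  structure(list(assays = assays,
                 effect_log2 = expand(effect_log2),
                 aca_vs_nac_log2 = expand(aca_vs_nac_log2),
                 replicate_sd = replicate_sd,
                 biological_sd = biological_sd,
                 n_per_group = n_per_group,
                 n_validation = n_validation,
                 n_replicates = as.integer(n_replicates),
                 censor_above = censor_above,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic specification: the study's assay panel
#'
#' The 16 target miRNAs with their literature expression directions in ACC,
#' plus the RNU48 and cel-miR-39 controls. Baseline Cts are field-realistic
#' choices: abundantly expressed controls (22-24 cycles), moderately
#' expressed targets (26-30 cycles) and a set of weakly expressed
#' down-regulated miRNAs (33-36 cycles) that occasionally cross the
#' 38-cycle detection ceiling, exercising the unmeasurable-well omission
#' rule downstream.
#'
#' @return a [synthetic_spec()] with discovery counts 10/10/10, validation
#'   counts 22 ACA / 21 ACC, effect_log2 = 2, replicate_sd = 0.25,
#'   biological_sd = 0.75, triplicate wells and censoring above 38 cycles.
#' @export
default_synthetic_spec <- function() {
  assays <- data.frame(
    name = c("hsa-miR-7", "hsa-miR-9", "hsa-miR-21", "hsa-miR-195",
             "hsa-miR-205", "hsa-miR-210", "hsa-miR-214", "hsa-miR-335",
             "hsa-miR-375", "hsa-miR-431", "hsa-miR-483-3p",
             "hsa-miR-483-5p", "hsa-miR-497", "hsa-miR-503",
             "hsa-miR-508", "hsa-miR-511", "RNU48", "cel-miR-39"),
    direction = c("down_in_ACC", "up_in_ACC", "up_in_ACC", "down_in_ACC",
                  "down_in_ACC", "up_in_ACC", "down_in_ACC", "down_in_ACC",
                  "down_in_ACC", "down_in_ACC", "up_in_ACC", "up_in_ACC",
                  "down_in_ACC", "up_in_ACC", "up_in_ACC", "down_in_ACC",
                  "control", "control"),
    baseline_ct = c(34, 28, 26, 27,
                    36, 28, 33, 34,
                    28, 36, 29,
                    27, 28, 29,
                    30, 35, 24, 22),
    stringsAsFactors = FALSE)
  synthetic_spec(assays)
}

dir_sign <- function(direction) {
  ifelse(direction == "up_in_ACC", 1,
         ifelse(direction == "down_in_ACC", -1, 0))
}

#' Generate a synthetic cohort Ct table
#'
#' Draws a full Ct table for one cohort under the generative model of
#' [synthetic_spec()]: per sample and assay a latent mean Ct
#' (baseline minus the group's log2 expression shift) plus biological noise,
#' per well technical noise, and per-well censoring above the detection
#' ceiling. Validation samples carry group `UNKNOWN` in the table; their
#' true labels are returned separately.
#'
#' @param spec a [synthetic_spec()].
#' @param cohort `"discovery"` or `"validation"`.
#' @param seed integer seed; defaults to the spec's.
#' @return list with elements `table` (a [ct_table()]) and `truth`
#'   (named character vector sample_id -> true group).
#' @export
generate_cohort <- function(spec, cohort = c("discovery", "validation"),
                            seed = spec$seed) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- if (cohort == "discovery") spec$n_per_group else spec$n_validation
  counts <- counts[counts > 0]
  groups <- rep(names(counts), counts)
  prefix <- if (cohort == "discovery") "D" else "V"
  ids <- sprintf("%s%02d", prefix, seq_along(groups))

  a <- spec$assays
  sgn <- dir_sign(a$direction)
  # log2 expression shift relative to NAC, per group x assay
  shift <- function(g) {
    switch(g,
           NAC = rep(0, nrow(a)),
           ACA = sgn * spec$aca_vs_nac_log2,
           ACC = sgn * (spec$aca_vs_nac_log2 + spec$effect_log2))
  }
  bio_sd <- ifelse(a$direction == "control",
                   spec$biological_sd / 3, spec$biological_sd)

  set.seed(child_seed(seed, paste0("simulate_", cohort)))
  n_rep <- spec$n_replicates
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- groups[i]
    latent <- a$baseline_ct - shift(g) + stats::rnorm(nrow(a), 0, bio_sd)
    wells <- rep(latent, each = n_rep) +
      stats::rnorm(nrow(a) * n_rep, 0, spec$replicate_sd)
    wells[wells > spec$censor_above] <- NA_real_
    recs[[i]] <- data.frame(
      sample_id = ids[i],
      group = if (cohort == "validation") "UNKNOWN" else g,
      assay = rep(a$name, each = n_rep),
      replicate = rep(seq_len(n_rep), times = nrow(a)),
      ct = wells, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, recs)
  # censoring may never produce a missing control; guard the invariant that
  # every sample keeps a measurable control by flooring controls at ceiling
  ctrl <- tab$assay %in% a$name[a$direction == "control"]
  tab$ct[ctrl & is.na(tab$ct)] <- spec$censor_above
  list(table = ct_table(tab,
                        control_assays = a$name[a$direction == "control"],
                        ct_max = max(40, spec$censor_above)),
       truth = stats::setNames(groups, ids))
}
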