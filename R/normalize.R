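#' Aggregate replicate wells into one Ct per (sample, assay)
#'
#' Collapses the triplicate (or k-replicate) wells of each sample x assay
#' pair to a single summary Ct, ignoring unmeasurable wells. A pair is
#' flagged missing only when every replicate is unmeasurable.
#'
#' @param table a [ct_table()].
#' @param policy `"mean"` (default) or `"median"` of the measurable wells.
#' @return data.frame with columns `sample_id`, `group`, `assay`, `ct`
#'   (`NA` when all replicates were unmeasurable).
#' @export
aggregate_replicates <- function(table, policy = c("mean", "median")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "ct_table"))
  f <- if (policy == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  }
  key <- interaction(table$sample_id, table$assay, drop = TRUE, sep = "\r")
  ct <- tapply(table$ct, key, f)
  parts <- do.call(rbind, strsplit(names(ct), "\r", fixed = TRUE))
  grp <- table$group[!duplicated(table$sample_id)]
  names(grp) <- table$sample_id[!duplicated(table$sample_id)]
  out <- data.frame(sample_id = parts[, 1L],
                    group = unname(grp[parts[, 1L]]),
                    assay = parts[, 2L],
                    ct = as.numeric(ct),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$assay), ]
  rownames(out) <- NULL
  out
}

#' Expression matrix container
#'
#' Samples x assays matrix of normalized log2 relative expression
#' (-deltaCt; higher = more expressed), with a missingness mask and the
#' sample group labels. Control assays are excluded by construction.
#'
#' @param values numeric matrix, samples in rows, target assays in columns.
#' @param mask logical matrix of the same shape; `TRUE` marks a missing
#'   (unmeasurable) entry.
#' @param groups named character vector sample_id -> group label.
#' @param control_ref named numeric vector sample_id -> the per-sample
#'   control reference Ct (kept for detection-floor imputation).
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, mask, groups, control_ref = NULL) {
  stopifnot(is.matrix(values), is.logical(mask),
            all(dim(values) == dim(mask)),
            nrow(values) == 0L || !is.null(rownames(values)),
            ncol(values) == 0L || !is.null(colnames(values)),
            all(rownames(values) %in% names(groups)))
  if (any(!is.finite(values[!mask]))) {
    stop("non-finite expression value outside the missing mask",
         call. = FALSE)
  }
  assert_group(groups[rownames(values)])
  structure(list(values = values, mask = mask,
                 groups = groups[rownames(values)],
                 control_ref = control_ref),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "Expression matrix: %d samples x %d assays, %d masked entries\n",
    nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Dimensions of an expression matrix
#' @param x an [expr_matrix()].
#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Delta-Ct normalization against the combined controls
#'
#' Per sample, the control reference is the geometric mean of the intrinsic
#' (RNU48) and spike-in (cel-miR-39) control Cts (an arithmetic-mean variant
#' is available, matching the convention of common qPCR normalization
#' software). Each target's deltaCt is its summary Ct minus the reference;
#' the stored expression value is -deltaCt, so up-regulation means larger
#' values. Targets with no measurable Ct stay masked.
#'
#' @param summary replicate-aggregated Ct data.frame from
#'   [aggregate_replicates()].
#' @param control_assays the two control assay names.
#' @param control_summary `"geometric"` or `"arithmetic"` mean of the two
#'   control Cts.
#' @return an [expr_matrix()] over the non-control assays.
#' @export
normalize_delta_ct <- function(summary, control_assays = DEFAULT_CONTROLS,
                               control_summary = c("geometric",
                                                   "arithmetic")) {
  control_summary <- match.arg(control_summary)
  stopifnot(all(c("sample_id", "assay", "ct") %in% names(summary)))
  samples <- sort(unique(summary$sample_id))
  is_ctrl <- summary$assay %in% control_assays
  targets <- sort(setdiff(unique(summary$assay), control_assays))

  ctrl <- summary[is_ctrl, ]
  ref <- vapply(samples, function(s) {
    cts <- ctrl$ct[ctrl$sample_id == s]
    if (length(cts) < length(control_assays) || any(is.na(cts))) {
      stop("sample ", s, " has a missing control summary", call. = FALSE)
    }
    if (control_summary == "geometric") exp(mean(log(cts))) else mean(cts)
  }, numeric(1))

  tgt <- summary[!is_ctrl, ]
  values <- matrix(NA_real_, length(samples), length(targets),
                   dimnames = list(samples, targets))
  idx <- cbind(match(tgt$sample_id, samples), match(tgt$assay, targets))
  values[idx] <- -(tgt$ct - ref[tgt$sample_id])
  mask <- is.na(values)
  values[mask] <- 0  # placeholder under the mask; never read
  groups <- stats::setNames(tgt$group[!duplicated(tgt$sample_id)],
                            tgt$sample_id[!duplicated(tgt$sample_id)])
  expr_matrix(values, mask, groups, control_ref = ref)
}

#' Apply the unmeasurable-measurement policy
#'
#' The study's rule (`omit_feature`): any assay with at least one masked
#' value across the analysis set is dropped entirely — down-regulated
#' miRNAs with no measurable Ct are omitted. The alternative
#' (`censor_fill`) keeps the assay and imputes masked cells at the
#' detection floor, i.e. expression -(ct_max - control_ref) for that
#' sample.
#'
#' @param matrix an [expr_matrix()].
#' @param policy `"omit_feature"` (default) or `"censor_fill"`.
#' @param ct_max cycle ceiling used by `censor_fill`.
#' @return an [expr_matrix()] with no masked entries.
#' @export
apply_missing_policy <- function(matrix,
                                 policy = c("omit_feature", "censor_fill"),
                                 ct_max = 40) {
  policy <- match.arg(policy)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!any(matrix$mask)) return(matrix)
  if (policy == "omit_feature") {
    keep <- colSums(matrix$mask) == 0L
    expr_matrix(matrix$values[, keep, drop = FALSE],
                matrix$mask[, keep, drop = FALSE],
                matrix$groups, matrix$control_ref)
  } else {
    if (is.null(matrix$control_ref)) {
      stop("censor_fill requires the per-sample control reference",
           call. = FALSE)
    }
    vals <- matrix$values
    floor_val <- -(ct_max - matrix$control_ref[rownames(vals)])
    idx <- which(matrix$mask, arr.ind = TRUE)
    vals[idx] <- floor_val[idx[, 1L]]
    expr_matrix(vals, matrix$mask & FALSE, matrix$groups,
                matrix$control_ref)
  }
}

#' Full normalization convenience wrapper
#'
#' Replicate aggregation, delta-Ct normalization and the missing policy in
#' one call, using the settings in a [run_config()].
#'
#' @param table a [ct_table()].
#' @param config a [run_config()].
#' @return an [expr_matrix()].
#' @export
normalize_ct_table <- function(table, config = run_config()) {
  summ <- aggregate_replicates(table, config$replicate_policy)
  em <- normalize_delta_ct(summ, config$control_assays,
                           config$control_summary)
  apply_missing_policy(em, config$missing_policy, config$ct_max)
}

#' Write an expression matrix to CSV (samples x assays, empty cell = missing)
#' @param matrix an [expr_matrix()].
#' @param path output CSV path.
#' @export
write_expr_matrix <- function(matrix, path) {
  vals <- matrix$values
  chr <- matrix(format(vals, digits = 15, trim = TRUE, scientific = FALSE),
                nrow(vals), dimnames = dimnames(vals))
  chr[matrix$mask] <- ""
  df <- data.frame(sample_id = rownames(vals),
                   group = unname(matrix$groups[rownames(vals)]),
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expr_matrix()]
#' @param path CSV path.
#' @return an [expr_matrix()].
#' @export
read_expr_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  assays <- setdiff(names(df), c("sample_id", "group"))
  vals <- suppressWarnings(
    vapply(assays, function(a) as.numeric(ifelse(df[[a]] == "", NA,
                                                 df[[a]])),
           numeric(nrow(df))))
  vals <- base::matrix(vals, nrow = nrow(df),
                       dimnames = list(df$sample_id, assays))
  mask <- is.na(vals)
  vals[mask] <- 0
  expr_matrix(vals, mask, stats::setNames(df$group, df$sample_id))
}

#' Restrict an expression matrix to a subset of samples and/or assays
#' @param matrix an [expr_matrix()].
#' @param samples,assays character vectors (NULL keeps all).
#' @return an [expr_matrix()].
#' @export
subset_expr <- function(matrix, samples = NULL, assays = NULL) {
  s <- if (is.null(samples)) rownames(matrix$values) else samples
  a <- if (is.null(assays)) colnames(matrix$values) else assays
  missing_a <- setdiff(a, colnames(matrix$values))
  if (length(missing_a) > 0L) {
    stop("assay(s) absent from expression matrix: ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  expr_matrix(matrix$values[s, a, drop = FALSE],
              matrix$mask[s, a, drop = FALSE],
              matrix$groups[s],
              if (is.null(matrix$control_ref)) NULL else
                matrix$control_ref[s])
}
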