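#' Construct and validate a Ct table
#'
#' A Ct table holds long-form raw RT-qPCR measurements: one row per
#' (sample, assay, replicate) well, with the cycle-threshold value in
#' cycles or `NA` for an unmeasurable ("Undetermined") well. Validation
#' enforces the structural invariants every downstream stage relies on:
#' unique wells, known group labels, both control assays present for every
#' sample, and Ct values in (0, ct_max].
#'
#' @param df data.frame with columns `sample_id`, `group`, `assay`,
#'   `replicate`, `ct` (`ct` may contain `NA`).
#' @param control_assays the two control assay names that must be present
#'   for every sample.
#' @param ct_max maximum admissible Ct in cycles.
#' @return the validated data.frame with class `ct_table`.
#' @export
ct_table <- function(df, control_assays = DEFAULT_CONTROLS, ct_max = 40) {
  required <- c("sample_id", "group", "assay", "replicate", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("Ct table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$assay <- as.character(df$assay)
  df$replicate <- as.integer(df$replicate)
  df$ct <- as.numeric(df$ct)

  assert_group(df$group)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate indices must be positive integers", call. = FALSE)
  }
  key <- paste(df$sample_id, df$assay, df$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- df[which(dup)[1L], ]
    stop(sprintf("duplicate well (%s, %s, %d)", first$sample_id,
                 first$assay, first$replicate), call. = FALSE)
  }
  ok <- is.na(df$ct) | (df$ct > 0 & df$ct <= ct_max)
  if (!all(ok)) {
    bad <- df[!ok, ][1L, ]
    stop(sprintf("Ct %.3f for (%s, %s) outside (0, %g]", bad$ct,
                 bad$sample_id, bad$assay, ct_max), call. = FALSE)
  }
  for (ctrl in control_assays) {
    have <- unique(df$sample_id[df$assay == ctrl])
    lacking <- setdiff(unique(df$sample_id), have)
    if (length(lacking) > 0L) {
      stop(sprintf("sample(s) without control assay %s: %s", ctrl,
                   paste(lacking, collapse = ", ")), call. = FALSE)
    }
  }
  class(df) <- c("ct_table", "data.frame")
  attr(df, "control_assays") <- control_assays
  attr(df, "ct_max") <- ct_max
  df
}

# Textual markers an instrument export may use for an unmeasurable well.
MISSING_MARKERS <- c("Undetermined", "NA", "")

#' Read a Ct table from CSV
#'
#' Expects a long-form comma-separated file with header columns
#' `sample_id, group, assay, replicate, ct`. The cell values
#' `"Undetermined"`, `"NA"` and the empty string are taken as unmeasurable
#' wells; every other `ct` cell must parse as decimal cycles.
#'
#' @param path CSV file path.
#' @param config a [run_config()] supplying control assay names and the
#'   Ct ceiling.
#' @return a validated [ct_table()].
#' @export
read_ct_table <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  required <- c("sample_id", "group", "assay", "replicate", "ct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("Ct CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ct_chr <- trimws(raw$ct)
  is_missing <- ct_chr %in% MISSING_MARKERS
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  unparsed <- !is_missing & is.na(ct_num)
  if (any(unparsed)) {
    stop(sprintf("unparseable ct value '%s' at row %d",
                 ct_chr[which(unparsed)[1L]], which(unparsed)[1L]),
         call. = FALSE)
  }
  ct_num[is_missing] <- NA_real_
  raw$ct <- ct_num
  ct_table(raw, control_assays = config$control_assays,
           ct_max = config$ct_max)
}

#' Write a Ct table to CSV
#'
#' Inverse of [read_ct_table()]: unmeasurable wells are written as
#' `"Undetermined"`, numeric cells with full precision, so that a
#' read-back round-trips losslessly.
#'
#' @param table a [ct_table()].
#' @param path output CSV path.
#' @export
write_ct_table <- function(table, path) {
  out <- as.data.frame(table)
  out$ct <- ifelse(is.na(out$ct), "Undetermined",
                   format(out$ct, digits = 15, trim = TRUE,
                          scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("Ct table: %d wells, %d samples, %d assays (%d unmeasurable)\n",
              nrow(x), length(unique(x$sample_id)),
              length(unique(x$assay)), sum(is.na(x$ct))))
  NextMethod()
}
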