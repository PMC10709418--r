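## Pre-processing of sorted-fraction count tables: control-based read
## removal followed by joint prevalence/abundance filtering. Both steps are
## contractions (ASVs are only ever dropped, counts never altered) and
## their order is fixed: decontamination first, then the joint filter.

#' Filtering parameters for the ASV pre-processing pipeline
#'
#' @param control_min_count reads in any single control sample that flag an
#'   ASV as a contaminant. Default 1: any control read triggers removal
#'   (the strictest reading of "appeared in a control"). Use `Inf` to
#'   disable decontamination.
#' @param min_prevalence minimum number of non-control samples an ASV must
#'   appear in (count > 0). Default 2.
#' @param min_rel_abund minimum maximum-per-sample relative abundance.
#'   Default 1e-4.
#'
#' An ASV is removed by [prevalence_abundance_filter()] only when it fails
#' *both* the prevalence and the abundance condition (conjunctive rule).
#'
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(control_min_count = 1,
                          min_prevalence = 2,
                          min_rel_abund = 1e-4) {
  if (!is.numeric(control_min_count) || control_min_count < 0)
    stop("configuration error: 'control_min_count' must be >= 0")
  check_nonneg(min_prevalence, "min_prevalence")
  check_nonneg(min_rel_abund, "min_rel_abund")
  if (min_rel_abund >= 1)
    stop("configuration error: 'min_rel_abund' must be < 1")
  structure(list(control_min_count = control_min_count,
                 min_prevalence = min_prevalence,
                 min_rel_abund = min_rel_abund),
            class = "filter_params")
}

#' Remove ASVs that appear in negative-control samples
#'
#' Any ASV reaching `control_min_count` reads in at least one control
#' sample (pre-sorting fluid, blank DNA extraction, or PCR control) is
#' removed from every sample; the control samples themselves are dropped
#' from the output. The list of removed ASVs is attached as attribute
#' `removed_asvs` so the run report can surface it.
#'
#' @param table a [sorted_counts()] object containing control samples. If
#'   no control samples are present the table passes through unchanged,
#'   with a warning.
#' @param params a [filter_params()] object.
#' @return A `sorted_counts` object without contaminant ASVs or control
#'   samples.
#' @export
remove_control_asvs <- function(table, params = filter_params()) {
  stopifnot(inherits(table, "sorted_counts"))
  ctrl <- is_control_sample(table)
  if (!any(ctrl)) {
    warning("no control samples present; decontamination skipped")
    out <- table
    attr(out, "removed_asvs") <- character(0)
    return(out)
  }
  ctrl_counts <- table$counts[, ctrl, drop = FALSE]
  flagged <- apply(ctrl_counts >= params$control_min_count, 1, any)
  removed <- rownames(table$counts)[flagged]
  out <- subset_samples(table, !ctrl)
  if (any(flagged)) out <- subset_asvs(out, !flagged)
  attr(out, "removed_asvs") <- removed
  out
}

#' Joint prevalence/abundance filter
#'
#' Removes an ASV only when it has *both* low prevalence (detected in fewer
#' than `min_prevalence` non-control samples) *and* low abundance (its
#' maximum per-sample relative abundance stays below `min_rel_abund`).
#' An ASV failing just one of the two conditions is retained.
#'
#' @inheritParams remove_control_asvs
#' @return A `sorted_counts` object; removed ASVs in attribute
#'   `removed_asvs`.
#' @export
prevalence_abundance_filter <- function(table, params = filter_params()) {
  stopifnot(inherits(table, "sorted_counts"))
  noncontrol <- !is_control_sample(table)
  cnt <- table$counts[, noncontrol, drop = FALSE]
  if (ncol(cnt) == 0L) stop("table has no non-control samples")
  prevalence <- rowSums(cnt > 0)
  totals <- colSums(cnt)
  rel <- sweep(cnt, 2, pmax(totals, 1), "/")
  max_rel <- apply(rel, 1, max)
  drop <- (prevalence < params$min_prevalence) &
    (max_rel < params$min_rel_abund)
  out <- if (any(drop)) subset_asvs(table, !drop) else table
  attr(out, "removed_asvs") <- rownames(table$counts)[drop]
  out
}

#' Per-sample relative abundances
#'
#' @param table a [sorted_counts()] object or a plain count matrix with
#'   samples in columns.
#' @return A numeric matrix of the same shape with each column summing to
#'   one.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "sorted_counts")) table$counts else
    as.matrix(table)
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("zero-total sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, totals, "/")
}

#' Run decontamination and the joint filter in their fixed order
#'
#' @inheritParams remove_control_asvs
#' @return A filtered `sorted_counts` object. Attributes
#'   `removed_by_controls` and `removed_by_filter` record the two removal
#'   lists.
#' @export
preprocess_counts <- function(table, params = filter_params()) {
  decontam <- remove_control_asvs(table, params)
  by_ctrl <- attr(decontam, "removed_asvs")
  out <- prevalence_abundance_filter(decontam, params)
  attr(out, "removed_by_controls") <- by_ctrl
  attr(out, "removed_by_filter") <- attr(out, "removed_asvs")
  attr(out, "removed_asvs") <- NULL
  out
}
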