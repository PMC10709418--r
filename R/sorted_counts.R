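## Container for sorted-fraction / bulk / control ASV count tables.
##
## A `sorted_counts` object bundles an ASV x sample integer count matrix
## with per-sample metadata (subject, household pair, IgA status, fraction
## type) and per-ASV taxonomy. It deliberately stays a plain list of base
## structures so tables round-trip losslessly through TSV.

#' Supported sorted-fraction sample types
#'
#' The vocabulary of `fraction_type` values: FACS sort gates (any/single/
#' double coated and non-coated), bulk feces, and the three negative
#' controls used for decontamination.
#'
#' @return character vector of fraction type names.
#' @export
fraction_types <- function() {
  c("any_IgA_coated", "any_IgM_coated",
    "single_IgA", "double_IgAIgG",
    "single_IgM", "double_IgMIgG",
    "single_IgG",
    "non_coated", "bulk",
    "control_presort", "control_blank", "control_pcr")
}

#' Fraction types that represent sorted Ig-coated gates
#' @return character vector.
#' @export
coated_fraction_types <- function() {
  c("any_IgA_coated", "any_IgM_coated", "single_IgA", "double_IgAIgG",
    "single_IgM", "double_IgMIgG", "single_IgG")
}

control_fraction_types <- function() {
  c("control_presort", "control_blank", "control_pcr")
}

#' Construct a sorted-fraction count table
#'
#' @param counts integer matrix, ASVs in rows (rownames = ASV ids), samples
#'   in columns (colnames = sample ids).
#' @param meta `data.frame` with one row per sample: `sample_id`,
#'   `subject_id`, `pair_id`, `iga_status` (`"IgA+"`/`"IgA-"`, `NA` for
#'   controls), `fraction_type` (see [fraction_types()]).
#' @param taxonomy `data.frame` with one row per ASV: `asv_id`, `phylum`,
#'   `family` and optionally `species`. Unknown taxa must be labelled
#'   explicitly (e.g. `"unclassified"`), never dropped.
#' @return An object of class `sorted_counts`.
#' @export
sorted_counts <- function(counts, meta, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  req <- c("sample_id", "subject_id", "pair_id", "iga_status", "fraction_type")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop("meta lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!setequal(meta$sample_id, colnames(counts)))
    stop("meta sample_id set does not match counts columns")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- setdiff(unique(meta$fraction_type), fraction_types())
  if (length(bad))
    stop("unknown fraction_type: ", paste(bad, collapse = ", "),
         "; supported: ", paste(fraction_types(), collapse = ", "))
  if (!all(c("asv_id", "phylum", "family") %in% names(taxonomy)))
    stop("taxonomy must have columns asv_id, phylum, family")
  missing_tax <- setdiff(rownames(counts), taxonomy$asv_id)
  if (length(missing_tax))
    stop("taxonomy does not cover ASVs: ",
         paste(utils::head(missing_tax, 5), collapse = ", "))
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$asv_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  noncontrol <- !(meta$fraction_type %in% control_fraction_types())
  if (any(is.na(meta$subject_id[noncontrol])) ||
      any(is.na(meta$pair_id[noncontrol])))
    stop("non-control samples must carry subject_id and pair_id")
  structure(list(counts = counts, meta = meta, taxonomy = taxonomy),
            class = "sorted_counts")
}

#' @export
print.sorted_counts <- function(x, ...) {
  cat(sprintf("sorted_counts: %d ASVs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("fraction types:",
      paste(sort(unique(x$meta$fraction_type)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sorted_counts <- function(x) dim(x$counts)

#' Subset a sorted_counts object
#'
#' @param x a `sorted_counts` object.
#' @param keep index or logical vector over samples (`subset_samples`) or
#'   ASVs (`subset_asvs`).
#' @return a `sorted_counts` object.
#' @export
subset_samples <- function(x, keep) {
  sorted_counts(x$counts[, keep, drop = FALSE],
                x$meta[keep, , drop = FALSE],
                x$taxonomy)
}

#' @rdname subset_samples
#' @export
subset_asvs <- function(x, keep) {
  counts <- x$counts[keep, , drop = FALSE]
  sorted_counts(counts, x$meta,
                x$taxonomy[match(rownames(counts), x$taxonomy$asv_id), ,
                           drop = FALSE])
}

#' Which samples of a sorted_counts table are negative controls?
#' @param x a `sorted_counts` object.
#' @return logical vector over samples.
#' @export
is_control_sample <- function(x) x$meta$fraction_type %in% control_fraction_types()

#' Write / read a sorted_counts object as TSV files
#'
#' Three tab-separated files are written under `dir`: `counts.tsv`
#' (ASV x sample), `samples.tsv` and `taxonomy.tsv`.
#'
#' @param x a `sorted_counts` object.
#' @param dir directory (created if needed).
#' @return `write_sorted_counts` returns `dir` invisibly;
#'   `read_sorted_counts` returns a `sorted_counts` object.
#' @export
write_sorted_counts <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cnt <- data.frame(asv_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sorted_counts
#' @export
read_sorted_counts <- function(dir) {
  cnt <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$asv_id
  meta <- utils::read.delim(file.path(dir, "samples.tsv"))
  tax <- utils::read.delim(file.path(dir, "taxonomy.tsv"))
  sorted_counts(counts, meta, tax)
}

#' Convert a sorted_counts object to / from BIOM
#'
#' Thin wrappers over the Bioconductor `biomformat` package (Suggests).
#'
#' @param x a `sorted_counts` object.
#' @param file path to a BIOM file.
#' @return `as_biom` returns a `biom` object; `write_biom_counts` writes
#'   `file` and returns it invisibly.
#' @export
as_biom <- function(x) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required for BIOM support")
  biomformat::make_biom(x$counts,
                        sample_metadata = x$meta,
                        observation_metadata = x$taxonomy)
}

#' @rdname as_biom
#' @export
write_biom_counts <- function(x, file) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required for BIOM support")
  biomformat::write_biom(as_biom(x), file)
  invisible(file)
}
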