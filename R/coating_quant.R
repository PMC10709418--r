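## Conversion of sorted-fraction compositions plus flow-derived loads into
## absolute coated loads per gram, family coating frequencies, and the
## fold/pseudocount ratios used for cohort comparisons.

#' Absolute coated load of a taxon
#'
#' Multiplies a taxon's relative abundance in the sorted coated fraction
#' by the flow-derived total coated load; summing over a complete
#' composition returns the coated load exactly.
#'
#' @param rel_abund_sorted relative abundance(s) in the sorted fraction,
#'   in `[0, 1]`.
#' @param coated_total_load flow-derived load of coated bacteria
#'   (bacteria/g).
#' @return bacteria/g, same length as `rel_abund_sorted`.
#' @export
taxon_coated_load <- function(rel_abund_sorted, coated_total_load) {
  stopifnot(all(rel_abund_sorted >= 0), all(rel_abund_sorted <= 1))
  check_nonneg(coated_total_load, "coated_total_load")
  rel_abund_sorted * coated_total_load
}

#' Family coating frequency
#'
#' Ratio of the coated load of a family to its total (bulk) load. The two
#' loads are independent estimates (sorted composition x coated flow load
#' vs. bulk composition x total flow load), so sampling noise can push the
#' ratio above 1; such estimates are capped at 1 with a warning, never
#' silently.
#'
#' @param coated_family_load bacteria/g coated within the family.
#' @param bulk_family_load total bacteria/g of the family (bulk relative
#'   abundance x total flow load). Zero gives a missing value, with a
#'   warning.
#' @return vector of frequencies in `[0, 1]` (NA where the bulk load is
#'   zero). Attribute `n_capped` counts capped estimates.
#' @export
family_coating_frequency <- function(coated_family_load, bulk_family_load) {
  stopifnot(length(coated_family_load) == length(bulk_family_load),
            all(coated_family_load >= 0), all(bulk_family_load >= 0))
  out <- rep(NA_real_, length(coated_family_load))
  ok <- bulk_family_load > 0
  if (any(!ok))
    warning(sum(!ok), " zero bulk family load(s); frequency undefined")
  out[ok] <- coated_family_load[ok] / bulk_family_load[ok]
  capped <- !is.na(out) & out > 1
  if (any(capped)) {
    warning(sum(capped), " coating frequency estimate(s) > 1 capped at 1")
    out[capped] <- 1
  }
  attr(out, "n_capped") <- sum(capped)
  out
}

#' Fold ratio of two positive quantities
#'
#' @param a,b positive reals (e.g. two group medians).
#' @return `a / b`.
#' @export
#' @examples
#' fold_ratio(7.2, 2.0) # 3.6
fold_ratio <- function(a, b) {
  if (any(b == 0)) stop("fold_ratio undefined for b = 0")
  a / b
}

#' Pseudocount-protected ratio of two loads
#'
#' Applies the transform `t(v) = 1 if v == 0 else v + 1` to both
#' arguments and returns `t(x) / t(y)`. The transform removes zero
#' denominators while leaving ratios of large loads essentially unchanged;
#' it is used for coated producer vs. non-producer load ratios.
#'
#' @param x,y non-negative loads.
#' @return positive ratio, vectorized over `x` and `y`.
#' @export
pseudocount_ratio <- function(x, y) {
  stopifnot(all(x >= 0), all(y >= 0))
  t <- function(v) ifelse(v == 0, 1, v + 1)
  t(x) / t(y)
}

#' Per-subject family-level coated loads and coating frequencies
#'
#' Joins, for one subject: the sorted coated-fraction composition (ASV
#' relative abundances), the flow-derived coated load, the bulk
#' composition and the flow-derived total load, and aggregates to family
#' level.
#'
#' @param sorted_rel named ASV relative abundances in the sorted coated
#'   fraction (sums to 1, or all zero when nothing was sorted).
#' @param bulk_rel named ASV relative abundances in bulk feces.
#' @param coated_load flow-derived coated bacteria/g for the matching
#'   sort gate (see [coated_load()]).
#' @param total_load flow-derived total bacteria/g.
#' @param taxonomy data.frame `asv_id`, `family` covering the ASVs.
#' @param include_zero_families keep families never observed coated
#'   (frequency 0) rather than dropping them. Default TRUE: the average
#'   over subjects then includes zeros.
#' @return data.frame of class `family_quant`: `family`, `coated_load`,
#'   `total_family_load`, `coating_frequency`.
#' @export
family_quant <- function(sorted_rel, bulk_rel, coated_load, total_load,
                         taxonomy, include_zero_families = TRUE) {
  stopifnot(!is.null(names(sorted_rel)), !is.null(names(bulk_rel)))
  fam_of <- function(ids) taxonomy$family[match(ids, taxonomy$asv_id)]
  coated_by_fam <- tapply(
    taxon_coated_load(sorted_rel, coated_load),
    fam_of(names(sorted_rel)), sum)
  bulk_by_fam <- tapply(bulk_rel * total_load, fam_of(names(bulk_rel)),
                        sum)
  families <- sort(unique(c(names(coated_by_fam), names(bulk_by_fam))))
  if (!include_zero_families)
    families <- families[families %in%
                           names(coated_by_fam)[coated_by_fam > 0]]
  cl <- ifelse(families %in% names(coated_by_fam),
               coated_by_fam[families], 0)
  bl <- ifelse(families %in% names(bulk_by_fam),
               bulk_by_fam[families], 0)
  freq <- suppressWarnings(family_coating_frequency(cl, bl))
  out <- data.frame(family = families, coated_load = as.numeric(cl),
                    total_family_load = as.numeric(bl),
                    coating_frequency = as.numeric(freq),
                    stringsAsFactors = FALSE)
  attr(out, "n_capped") <- attr(freq, "n_capped")
  class(out) <- c("family_quant", "data.frame")
  out
}

#' Cohort-level average coated fraction per family
#'
#' Averages the coated and total family loads across subjects (zeros
#' included) and derives the family's average coating frequency as the
#' ratio of the two averages. For sparse families this ratio-of-averages
#' is far more stable than averaging per-subject ratios, whose
#' denominators can be a handful of reads; the per-subject ratios remain
#' available in the input table.
#'
#' @param family_quant_tbl row-bound per-subject [family_quant()] tables
#'   (must carry a `subject_id` column; an optional `iga_status` column
#'   splits the summary by status).
#' @return data.frame per family (and status, when present): mean
#'   `coated_load`, mean `total_family_load`, `coating_frequency` =
#'   ratio of the means (capped at 1 with a warning), `n_subjects`.
#' @export
family_coating_summary <- function(family_quant_tbl) {
  stopifnot(all(c("family", "coated_load", "total_family_load",
                  "subject_id") %in% names(family_quant_tbl)))
  by <- list(family = family_quant_tbl$family)
  if ("iga_status" %in% names(family_quant_tbl))
    by$iga_status <- family_quant_tbl$iga_status
  agg <- stats::aggregate(
    family_quant_tbl[, c("coated_load", "total_family_load")], by, mean)
  agg$n_subjects <- stats::aggregate(
    family_quant_tbl$subject_id, by,
    function(s) length(unique(s)))$x
  agg$coating_frequency <- as.numeric(suppressWarnings(
    family_coating_frequency(agg$coated_load, agg$total_family_load)))
  agg
}
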