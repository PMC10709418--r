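## End-to-end cohort analysis: flow quantification per subject,
## decontamination and filtering of the sorted count tables, coating
## classification, family-level coated loads and frequencies, capability
## calls, and the paired statistics — collected into one run report.

#' Run the full multi-Ig coating analysis on a cohort bundle
#'
#' @param bundle a raw-input bundle as produced by [generate_cohort()]
#'   (`$bundle`): sorted/bulk/control counts, per-subject event tables,
#'   FMO events, flow acquisition metadata and KO profiles.
#' @param params [filter_params()] for the ASV pipeline.
#' @param rules [load_ligand_rules()] ruleset.
#' @param fmo_quantile FMO quantile for gate thresholds.
#' @param min_count minimum reads for presence calls.
#' @return list of class `cohort_report`: `thresholds`, `flow` (per-subject
#'   loads and coating fractions), `counts_filtered`, `classification`,
#'   `summary` (a [summarize_categories()] result), `family_quant`
#'   (subject x family coated loads/frequencies), `capability_calls`,
#'   `producer_summary`, `tests` (tidy table of paired tests) and
#'   `fold_coating` (ratio of median coated percentages, IgA+ : IgA-).
#' @export
run_cohort_analysis <- function(bundle, params = filter_params(),
                                rules = load_ligand_rules(),
                                fmo_quantile = 0.999, min_count = 1) {
  thresholds <- derive_thresholds(bundle$fmo_events,
                                  quantile = fmo_quantile)
  meta <- bundle$counts$meta
  subj_meta <- unique(meta[!is.na(meta$subject_id),
                           c("subject_id", "pair_id", "iga_status")])

  ## flow layer -------------------------------------------------------
  flow <- list()
  for (i in seq_len(nrow(subj_meta))) {
    sid <- subj_meta$subject_id[i]
    fm <- bundle$flow_meta[bundle$flow_meta$subject_id == sid, ]
    prof <- classify_events(bundle$events[[sid]], thresholds)
    load <- absolute_load(prof$n_gated, prof$n_beads, fm$beads_added,
                          fm$dilution_factor, fm$sample_mass)
    fr <- coating_fractions(prof)
    pct_any <- 100 * (1 - prof$counts[["none"]] / prof$n_gated)
    flow[[sid]] <- data.frame(
      subject_id = sid, pair_id = subj_meta$pair_id[i],
      iga_status = subj_meta$iga_status[i],
      total_load = load$load,
      pct_iga = 100 * fr[["iga"]], pct_igm = 100 * fr[["igm"]],
      pct_igg = 100 * fr[["igg"]], pct_any_ig = pct_any,
      load_any_iga = coated_load(prof, load, "iga"),
      load_any_igm = coated_load(prof, load, "igm"),
      load_any_ig = load$load * pct_any / 100,
      stringsAsFactors = FALSE)
  }
  flow <- do.call(rbind, flow)
  rownames(flow) <- NULL

  ## ASV pipeline + classification -------------------------------------
  filtered <- preprocess_counts(bundle$counts, params)
  presence <- presence_matrix(filtered, min_count = min_count)
  classification <- classify_asvs(presence)
  summary <- summarize_categories(classification)

  ## family-level quantification ---------------------------------------
  rel <- relative_abundance_safe(filtered)
  fq <- list()
  taxon_loads <- list()
  for (i in seq_len(nrow(subj_meta))) {
    sid <- subj_meta$subject_id[i]
    status <- subj_meta$iga_status[i]
    coated_fr <- if (status == "IgA+") "any_IgA_coated" else
      "any_IgM_coated"
    coated_sample <- filtered$meta$sample_id[
      filtered$meta$subject_id == sid &
        filtered$meta$fraction_type == coated_fr]
    bulk_sample <- filtered$meta$sample_id[
      filtered$meta$subject_id == sid &
        filtered$meta$fraction_type == "bulk"]
    if (!length(coated_sample) || !length(bulk_sample)) next
    srel <- rel[, coated_sample[1]]
    brel <- rel[, bulk_sample[1]]
    fl <- flow[flow$subject_id == sid, ]
    cload <- if (status == "IgA+") fl$load_any_iga else fl$load_any_igm
    qt <- family_quant(srel, brel, cload, fl$total_load,
                       filtered$taxonomy)
    qt$subject_id <- sid
    qt$iga_status <- status
    fq[[sid]] <- qt
    taxon_loads[[sid]] <- data.frame(
      subject_id = sid, taxon_id = names(srel),
      coated_load = taxon_coated_load(srel, cload),
      total_load = brel * fl$total_load, stringsAsFactors = FALSE)
  }
  family_quant_tbl <- do.call(rbind, fq)
  rownames(family_quant_tbl) <- NULL
  taxon_loads <- do.call(rbind, taxon_loads)
  rownames(taxon_loads) <- NULL

  ## capability calls ---------------------------------------------------
  calls <- call_ligands_all(bundle$ko_profiles, rules)
  producer_summary <- if (!is.null(taxon_loads))
    producer_coating_summary(calls, taxon_loads) else NULL

  ## paired statistics --------------------------------------------------
  wide <- function(col) {
    plus <- flow[flow$iga_status == "IgA+", ]
    minus <- flow[flow$iga_status == "IgA-", ]
    minus <- minus[match(plus$pair_id, minus$pair_id), ]
    list(plus = plus[[col]], minus = minus[[col]])
  }
  tests <- list(
    total_load = with(wide("total_load"), paired_wilcoxon(plus, minus)),
    pct_any_ig = with(wide("pct_any_ig"), paired_wilcoxon(plus, minus)),
    pct_igm = with(wide("pct_igm"), paired_wilcoxon(plus, minus)),
    pct_igg = with(wide("pct_igg"), paired_wilcoxon(plus, minus)))
  tests <- adjust_results(tests)
  pm <- wide("pct_any_ig")
  fold_coating <- fold_ratio(stats::median(pm$plus),
                             stats::median(pm$minus))

  ## E. coli-like taxon load, when flagged in the taxonomy --------------
  ecoli <- NULL
  tax <- bundle$counts$taxonomy
  ec_ids <- tax$asv_id[!is.na(tax$species) &
                         tax$species == "Escherichia coli"]
  if (length(ec_ids) && !is.null(taxon_loads)) {
    ec <- taxon_loads[taxon_loads$taxon_id %in% ec_ids, ]
    ec_load <- tapply(ec$total_load, ec$subject_id, sum)
    flow$ecoli_load <- as.numeric(ec_load[flow$subject_id])
    w <- wide("ecoli_load")
    ecoli <- list(
      test = paired_wilcoxon(w$minus, w$plus),
      fold_minus_over_plus = fold_ratio(
        stats::median(w$minus, na.rm = TRUE),
        stats::median(w$plus, na.rm = TRUE)))
  }

  structure(list(thresholds = thresholds, flow = flow,
                 counts_filtered = filtered, presence = presence,
                 classification = classification, summary = summary,
                 family_quant = family_quant_tbl,
                 family_summary = if (!is.null(family_quant_tbl))
                   family_coating_summary(family_quant_tbl) else NULL,
                 capability_calls = calls,
                 producer_summary = producer_summary,
                 tests = results_table(tests),
                 fold_coating = fold_coating, ecoli = ecoli,
                 params = params),
            class = "cohort_report")
}

# relative abundance tolerating all-zero samples (returned as zeros)
relative_abundance_safe <- function(table) {
  counts <- table$counts
  totals <- colSums(counts)
  sweep(counts, 2, pmax(totals, 1), "/")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Multi-Ig coating cohort report\n")
  cat(sprintf("  subjects: %d (%d pairs)\n", nrow(x$flow),
              length(unique(x$flow$pair_id))))
  cat(sprintf("  median coated %%: IgA+ %.2f, IgA- %.2f (fold %.2f)\n",
              stats::median(x$flow$pct_any_ig[x$flow$iga_status == "IgA+"]),
              stats::median(x$flow$pct_any_ig[x$flow$iga_status == "IgA-"]),
              x$fold_coating))
  print(x$summary)
  cat("Paired tests:\n")
  print(x$tests)
  invisible(x)
}
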