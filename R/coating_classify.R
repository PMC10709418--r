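## Set-theoretic classification of ASVs into coating categories across
## household pairs, with taxonomic rollups and sorted-fraction prevalence
## summaries.
##
## Categories (cohort level): an ASV is coated-in-IgA+ when it is present
## in at least one coated sorted fraction of at least one IgA+ subject,
## and likewise coated-in-IgA- via IgM-based sorts; `shared` means both,
## `iga_only` / `igm_only` exactly one, `strictly_non_coated` means seen
## in a non-coated fraction and never in any coated fraction of any
## subject, and `unobserved` covers ASVs never detected in any sorted
## fraction.

coating_categories <- function() {
  c("shared", "iga_only", "igm_only", "strictly_non_coated", "unobserved")
}

#' Presence of each ASV per sorted-fraction class
#'
#' @param table a pre-processed [sorted_counts()] object (after
#'   [preprocess_counts()]).
#' @param min_count minimum reads in a single sample to count as present
#'   (default 1; raise to guard against index hopping).
#' @return object of class `presence_matrix`: `cohort` — logical array
#'   ASV x fraction class x IgA status (present in >= 1 sample of that
#'   class/status); `by_subject` — logical array ASV x subject x class;
#'   plus `taxonomy` and subject metadata for downstream summaries.
#' @export
presence_matrix <- function(table, min_count = 1) {
  stopifnot(inherits(table, "sorted_counts"))
  check_positive(min_count, "min_count", integer = TRUE)
  keep <- !is_control_sample(table) & table$meta$fraction_type != "bulk"
  cnt <- table$counts[, keep, drop = FALSE]
  meta <- table$meta[keep, , drop = FALSE]
  bad <- setdiff(unique(meta$fraction_type), fraction_types())
  if (length(bad)) stop("unknown fraction class: ", paste(bad, collapse = ", "))
  classes <- sort(unique(meta$fraction_type))
  statuses <- c("IgA+", "IgA-")
  det <- cnt >= min_count
  cohort <- array(FALSE,
                  dim = c(nrow(cnt), length(classes), length(statuses)),
                  dimnames = list(rownames(cnt), classes, statuses))
  for (cl in classes) for (st in statuses) {
    sel <- meta$fraction_type == cl & meta$iga_status == st
    if (any(sel))
      cohort[, cl, st] <- rowSums(det[, sel, drop = FALSE]) > 0
  }
  subjects <- unique(meta$subject_id)
  by_subject <- array(FALSE,
                      dim = c(nrow(cnt), length(subjects), length(classes)),
                      dimnames = list(rownames(cnt), subjects, classes))
  for (s in subjects) for (cl in classes) {
    sel <- meta$subject_id == s & meta$fraction_type == cl
    if (any(sel))
      by_subject[, s, cl] <- rowSums(det[, sel, drop = FALSE]) > 0
  }
  subj_meta <- unique(meta[, c("subject_id", "pair_id", "iga_status")])
  structure(list(cohort = cohort, by_subject = by_subject,
                 taxonomy = table$taxonomy, subjects = subj_meta),
            class = "presence_matrix")
}

# coated presence per status from a cohort-level presence array
coated_by_status <- function(cohort_arr, status) {
  cls <- intersect(dimnames(cohort_arr)[[2]], coated_fraction_types())
  if (!length(cls)) return(rep(FALSE, dim(cohort_arr)[1]))
  apply(cohort_arr[, cls, status, drop = FALSE], 1, any)
}

#' Classify ASVs into coating categories
#'
#' @param presence a [presence_matrix()].
#' @return data.frame of class `coating_classification` with `asv_id`,
#'   `category` (see [coating_categories()]), `phylum`, `family`.
#' @export
classify_asvs <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  arr <- presence$cohort
  coated_a <- coated_by_status(arr, "IgA+")
  coated_m <- coated_by_status(arr, "IgA-")
  non_cls <- intersect(dimnames(arr)[[2]], "non_coated")
  in_noncoated <- if (length(non_cls))
    apply(arr[, non_cls, , drop = FALSE], 1, any) else
      rep(FALSE, dim(arr)[1])
  category <- rep("unobserved", dim(arr)[1])
  category[coated_a & coated_m] <- "shared"
  category[coated_a & !coated_m] <- "iga_only"
  category[!coated_a & coated_m] <- "igm_only"
  category[!coated_a & !coated_m & in_noncoated] <- "strictly_non_coated"
  tax <- presence$taxonomy
  out <- data.frame(asv_id = dimnames(arr)[[1]], category = category,
                    stringsAsFactors = FALSE)
  out$phylum <- tax$phylum[match(out$asv_id, tax$asv_id)]
  out$family <- tax$family[match(out$asv_id, tax$asv_id)]
  class(out) <- c("coating_classification", "data.frame")
  out
}

#' Per-household-pair coating categories
#'
#' Same rule as [classify_asvs()] applied within each household pair.
#'
#' @param presence a [presence_matrix()].
#' @return data.frame `asv_id` x one category column per pair.
#' @export
classify_asvs_per_pair <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  bs <- presence$by_subject
  subj <- presence$subjects
  classes <- dimnames(bs)[[3]]
  coated_cls <- intersect(classes, coated_fraction_types())
  out <- data.frame(asv_id = dimnames(bs)[[1]], stringsAsFactors = FALSE)
  for (p in unique(subj$pair_id)) {
    members <- subj$subject_id[subj$pair_id == p]
    st <- subj$iga_status[subj$pair_id == p]
    pres_of <- function(sids, cls) {
      if (!length(sids) || !length(cls)) return(rep(FALSE, nrow(out)))
      apply(bs[, sids, cls, drop = FALSE], 1, any)
    }
    coated_a <- pres_of(members[st == "IgA+"], coated_cls)
    coated_m <- pres_of(members[st == "IgA-"], coated_cls)
    in_nc <- pres_of(members, intersect(classes, "non_coated"))
    category <- rep("unobserved", nrow(out))
    category[coated_a & coated_m] <- "shared"
    category[coated_a & !coated_m] <- "iga_only"
    category[!coated_a & coated_m] <- "igm_only"
    category[!coated_a & !coated_m & in_nc] <- "strictly_non_coated"
    out[[p]] <- category
  }
  out
}

#' Summarize a coating classification
#'
#' Counts and printed-precision percentages per category (relative to the
#' coated total: shared + IgA-only + IgM-only), with per-phylum and
#' per-family rollups of the coated ASVs. Percentages of 10 or more print
#' as integers, below 10 with one decimal (see [round_pct()]).
#'
#' @param classification a [classify_asvs()] result, or any data.frame
#'   with columns `asv_id`, `category`, `phylum`, `family`.
#' @return list of class `category_summary`: `category_counts`,
#'   `coated_total`, `category_pct`, `phylum` and `family` rollup
#'   data.frames (sorted by descending count).
#' @export
summarize_categories <- function(classification) {
  stopifnot(nrow(classification) > 0,
            all(c("category", "phylum", "family") %in%
                  names(classification)))
  cats <- coating_categories()
  counts <- vapply(cats, function(cc) sum(classification$category == cc),
                   integer(1))
  coated_cats <- c("shared", "iga_only", "igm_only")
  coated_total <- sum(counts[coated_cats])
  category_pct <- if (coated_total > 0)
    round_pct(100 * counts[coated_cats] / coated_total) else
      stats::setNames(rep(NA_real_, 3), coated_cats)
  coated <- classification[classification$category %in% coated_cats, ,
                           drop = FALSE]
  rollup <- function(key) {
    if (!nrow(coated))
      return(data.frame(level = character(0), n = integer(0),
                        pct_of_coated = numeric(0)))
    tab <- sort(table(coated[[key]]), decreasing = TRUE)
    data.frame(level = names(tab), n = as.integer(tab),
               pct_of_coated = round_pct(100 * as.integer(tab) /
                                           coated_total),
               stringsAsFactors = FALSE)
  }
  structure(list(category_counts = counts, coated_total = coated_total,
                 category_pct = category_pct,
                 phylum = rollup("phylum"), family = rollup("family")),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Coated ASVs:", x$coated_total, "\n")
  for (cc in c("shared", "iga_only", "igm_only"))
    cat(sprintf("  %-20s %5d (%s%%)\n", cc, x$category_counts[[cc]],
                x$category_pct[[cc]]))
  cat(sprintf("  %-20s %5d\n", "strictly_non_coated",
              x$category_counts[["strictly_non_coated"]]))
  cat("Top phyla of coated ASVs:\n")
  print(utils::head(x$phylum, 5))
  invisible(x)
}

#' Joint share of the top-n families among coated ASVs
#'
#' @param summary a [summarize_categories()] result.
#' @param n number of families.
#' @return printed-precision percentage of coated ASVs covered by the `n`
#'   most ASV-rich families.
#' @export
top_family_share <- function(summary, n = 3) {
  stopifnot(inherits(summary, "category_summary"))
  fam <- summary$family
  round_pct(100 * sum(utils::head(fam$n, n)) / summary$coated_total)
}

#' Prevalence of coated bacterial families per sorted fraction
#'
#' For each family and each coated sorted-fraction class, the percentage
#' of subjects (with at least one sample of that class) in which at least
#' one ASV of the family was detected. Also returns, per subject and
#' class, the fraction of detected families — the per-subject overall
#' prevalence used for comparing Ig combinations.
#'
#' @param presence a [presence_matrix()] built from single/double coated
#'   fraction samples.
#' @param classes fraction classes to summarize; default every coated
#'   class present.
#' @return list of class `fraction_prevalence`: `by_family` (data.frame
#'   family x class, `prevalence_pct`), `by_subject` (data.frame subject,
#'   class, `families_detected`, `prop_families`).
#' @export
fraction_prevalence <- function(presence, classes = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  bs <- presence$by_subject
  all_classes <- dimnames(bs)[[3]]
  classes <- classes %||% intersect(all_classes, coated_fraction_types())
  missing_cls <- setdiff(classes, all_classes)
  if (length(missing_cls))
    stop("fraction class not in presence matrix: ",
         paste(missing_cls, collapse = ", "))
  fam <- presence$taxonomy$family[match(dimnames(bs)[[1]],
                                        presence$taxonomy$asv_id)]
  families <- sort(unique(fam))
  subj <- presence$subjects
  by_family <- expand.grid(family = families, class = classes,
                           stringsAsFactors = FALSE)
  by_family$prevalence_pct <- NA_real_
  by_subject <- NULL
  for (cl in classes) {
    sids <- subj$subject_id
    det_fs <- vapply(sids, function(s) {
      pres <- bs[, s, cl]
      vapply(families, function(f) any(pres & fam == f), logical(1))
    }, logical(length(families)))
    if (length(families) == 1L)
      det_fs <- matrix(det_fs, nrow = 1,
                       dimnames = list(families, sids))
    relevant <- relevant_subjects_for_class(cl, subj)
    for (f in families) {
      i <- which(by_family$family == f & by_family$class == cl)
      by_family$prevalence_pct[i] <-
        100 * mean(det_fs[f, relevant, drop = TRUE])
    }
    by_subject <- rbind(by_subject, data.frame(
      subject_id = relevant, class = cl,
      families_detected = colSums(det_fs[, relevant, drop = FALSE]),
      prop_families = colMeans(det_fs[, relevant, drop = FALSE]),
      stringsAsFactors = FALSE))
  }
  structure(list(by_family = by_family, by_subject = by_subject),
            class = "fraction_prevalence")
}

# IgA-based gates are sorted from IgA+ subjects, IgM-based from IgA-;
# IgG-only and non-coated gates exist for both statuses.
relevant_subjects_for_class <- function(cl, subj) {
  if (cl %in% c("any_IgA_coated", "single_IgA", "double_IgAIgG"))
    subj$subject_id[subj$iga_status == "IgA+"]
  else if (cl %in% c("any_IgM_coated", "single_IgM", "double_IgMIgG"))
    subj$subject_id[subj$iga_status == "IgA-"]
  else subj$subject_id
}
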