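## Rule-based capability calling from KEGG-ortholog profiles: flagellin,
## penta-/hexa-acylated LPS (Raetz pathway core plus the secondary
## acyltransferase extension), and butyrate production. Rules are
## AND-of-OR requirement groups loaded from an editable JSON table;
## butyrate additionally requires at least one complete precursor route.

ko_ok <- function(ko) grepl("^K[0-9]{5}$", ko)

validate_groups <- function(groups, what) {
  if (!length(groups)) stop("capability '", what, "' has no groups")
  for (g in groups) {
    if (!length(g)) stop("empty requirement group in '", what, "'")
    bad <- g[!ko_ok(g)]
    if (length(bad))
      stop("malformed KO id(s) in '", what, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Load a capability rule table
#'
#' @param path JSON rule file; defaults to the table shipped with the
#'   package. Each capability holds `groups` (list of alternative-KO
#'   vectors, all of which must be hit) and optionally `routes` (list of
#'   group-lists, at least one of which must be fully satisfied) plus a
#'   `map` provenance string naming the KEGG map the defaults were
#'   curated from.
#' @return named list of class `ligand_rules` with capabilities
#'   `flagellin`, `lps_core`, `lps_hexa_extension`, `butyrate`.
#' @export
load_ligand_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ligand_rules.json",
                                package = "igcoat")
  raw <- jsonlite::read_json(path)
  raw[["_comment"]] <- NULL
  rules <- lapply(names(raw), function(nm) {
    cap <- raw[[nm]]
    groups <- lapply(cap$groups, function(g) unlist(g, use.names = FALSE))
    validate_groups(groups, nm)
    routes <- lapply(cap$routes %||% list(), function(rt)
      lapply(rt, function(g) unlist(g, use.names = FALSE)))
    for (rt in routes) validate_groups(rt, paste0(nm, " route"))
    list(groups = groups, routes = routes, map = cap$map %||% NA_character_)
  })
  names(rules) <- names(raw)
  needed <- c("flagellin", "lps_core", "lps_hexa_extension", "butyrate")
  missing_cap <- setdiff(needed, names(rules))
  if (length(missing_cap))
    stop("configuration error: ruleset lacks capabilities: ",
         paste(missing_cap, collapse = ", "))
  structure(rules, class = "ligand_rules")
}

#' Evaluate an AND-of-OR requirement rule against a KO profile
#'
#' @param profile character vector of KO identifiers (`"K"` + 5 digits).
#' @param groups list of character vectors; each group is satisfied when
#'   the profile intersects it, the rule when every group is satisfied.
#' @return logical scalar.
#' @export
evaluate_capability <- function(profile, groups) {
  bad <- profile[!ko_ok(profile)]
  if (length(bad))
    stop("malformed KO id(s) in profile: ", paste(bad, collapse = ", "))
  validate_groups(groups, "rule")
  all(vapply(groups, function(g) any(g %in% profile), logical(1)))
}

# groups AND (no routes, or >=1 route with all its groups satisfied)
capability_satisfied <- function(profile, cap) {
  base <- evaluate_capability(profile, cap$groups)
  if (!base || !length(cap$routes)) return(base)
  any(vapply(cap$routes, function(rt) evaluate_capability(profile, rt),
             logical(1)))
}

#' Call ligand / butyrate capabilities for one taxon
#'
#' @param profile character vector of KO ids for the taxon.
#' @param rules a [load_ligand_rules()] ruleset.
#' @return list of class `capability_call`: `flagellin` (logical), `lps`
#'   (`"none"`, `"penta"` or `"hexa"`), `butyrate` (logical). A taxon
#'   calls `hexa` only when the LPS core pathway is also complete.
#' @export
call_ligands <- function(profile, rules = load_ligand_rules()) {
  stopifnot(inherits(rules, "ligand_rules"))
  core <- capability_satisfied(profile, rules$lps_core)
  lps <- if (!core) "none" else if (
    capability_satisfied(profile, rules$lps_hexa_extension)) "hexa" else
      "penta"
  structure(list(
    flagellin = capability_satisfied(profile, rules$flagellin),
    lps = lps,
    butyrate = capability_satisfied(profile, rules$butyrate)),
    class = "capability_call")
}

#' Call capabilities for every taxon in a long KO table
#'
#' @param ko_profiles data.frame with columns `taxon_id`, `ko`.
#' @param rules a [load_ligand_rules()] ruleset.
#' @return data.frame `taxon_id`, `flagellin`, `lps`, `butyrate`.
#' @export
call_ligands_all <- function(ko_profiles, rules = load_ligand_rules()) {
  stopifnot(all(c("taxon_id", "ko") %in% names(ko_profiles)))
  split_kos <- split(ko_profiles$ko, ko_profiles$taxon_id)
  calls <- lapply(split_kos, call_ligands, rules = rules)
  data.frame(taxon_id = names(calls),
             flagellin = vapply(calls, `[[`, logical(1), "flagellin"),
             lps = vapply(calls, `[[`, character(1), "lps"),
             butyrate = vapply(calls, `[[`, logical(1), "butyrate"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Join capability calls to coated-load quantities
#'
#' For each capability (`flagellin`, `lps_penta`, `lps_hexa`, `butyrate`)
#' and each subject: the percentage of taxa predicted to hold the
#' potential, the coating frequency among producers (coated load of
#' producers / total load of producers), and the pseudocount-protected
#' ratio of coated-producer to coated-non-producer load.
#'
#' @param calls a [call_ligands_all()] result.
#' @param taxon_loads data.frame with one row per subject x taxon:
#'   `subject_id`, `taxon_id`, `coated_load`, `total_load` (bacteria/g).
#' @return data.frame `subject_id`, `capability`, `pct_producers`,
#'   `producer_coating_freq`, `coated_ratio`.
#' @export
producer_coating_summary <- function(calls, taxon_loads) {
  stopifnot(all(c("taxon_id", "lps") %in% names(calls)),
            all(c("subject_id", "taxon_id", "coated_load", "total_load")
                %in% names(taxon_loads)))
  shared <- intersect(calls$taxon_id, taxon_loads$taxon_id)
  if (!length(shared)) {
    orphans <- utils::head(unique(taxon_loads$taxon_id), 5)
    stop("capability calls and load table share no taxa; e.g. loads have: ",
         paste(orphans, collapse = ", "))
  }
  producer_flags <- list(
    flagellin = stats::setNames(calls$flagellin, calls$taxon_id),
    lps_penta = stats::setNames(calls$lps == "penta", calls$taxon_id),
    lps_hexa = stats::setNames(calls$lps == "hexa", calls$taxon_id),
    butyrate = stats::setNames(calls$butyrate, calls$taxon_id))
  out <- list()
  for (cap in names(producer_flags)) {
    flag <- producer_flags[[cap]]
    for (s in unique(taxon_loads$subject_id)) {
      tl <- taxon_loads[taxon_loads$subject_id == s &
                          taxon_loads$taxon_id %in% names(flag), ,
                        drop = FALSE]
      is_prod <- flag[tl$taxon_id]
      prod_total <- sum(tl$total_load[is_prod])
      out[[length(out) + 1L]] <- data.frame(
        subject_id = s, capability = cap,
        pct_producers = 100 * mean(is_prod),
        producer_coating_freq = if (prod_total > 0)
          sum(tl$coated_load[is_prod]) / prod_total else NA_real_,
        coated_ratio = pseudocount_ratio(sum(tl$coated_load[is_prod]),
                                         sum(tl$coated_load[!is_prod])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
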