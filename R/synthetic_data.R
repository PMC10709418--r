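## Synthetic cohort generator.
##
## Emulates the study design the analysis assumes: household pairs of one
## IgA-deficient (IgA-) and one IgA-sufficient (IgA+) subject; per-ASV
## per-isotype coating probabilities with IgA coating exactly absent in
## IgA- subjects; bead-spiked flow acquisitions; FACS-sorted fraction
## compositions with configurable sort purity; contaminant reads shared
## between sorted samples and negative controls; and multinomial
## sequencing counts. Every latent quantity is returned as ground truth so
## downstream stages can be validated end to end.

#' Configuration for a synthetic multi-Ig coating cohort
#'
#' @param n_pairs number of household pairs (one IgA+ and one IgA- subject
#'   each). Default 16, the size of the sort-seq subcohort.
#' @param n_asvs number of community ASVs.
#' @param mean_load geometric-mean total bacterial load, bacteria per gram
#'   feces. Default 2e10.
#' @param coating_prob_priors per-isotype Beta parameters (list with
#'   elements `iga`, `igm`, `igg`, each `c(shape1, shape2)`) for the
#'   per-ASV coating probabilities of coated ASVs.
#' @param category_probs probability that an ASV is truly `shared`
#'   (IgA-coated in IgA+ and IgM-coated in IgA-), `iga_only`, `igm_only`,
#'   or `non_coated`. Defaults reflect roughly half of gut ASVs being
#'   coated, with the coated half split about evenly between the three
#'   coated categories.
#' @param iga_deficient_isotype_shift list with `igm` and `igg`: the
#'   fraction of a shared ASV's IgA coating probability that reappears as
#'   IgM (and extra IgG) coating in the IgA- household member. The default
#'   (0.25, 0.05) reproduces a severalfold lower overall coating in IgA-
#'   subjects.
#' @param igg_coating_prob probability a coated ASV is additionally
#'   IgG-coated (drives the double-IgAIgG / double-IgMIgG fractions).
#' @param seq_depth reads per sorted or bulk sample.
#' @param contamination_rate fraction of reads in sorted samples drawn from
#'   the contaminant ASV pool; controls receive
#'   `round(seq_depth * contamination_rate)` reads from the same pool.
#' @param sort_purity probability a sorted read's source bacterium truly
#'   belongs to the target gate; the remainder
#'   `1 - sort_purity - contamination_rate` is carry-over of bulk
#'   community.
#' @param beads_added counting beads spiked per tube.
#' @param n_events flow events recorded per acquisition. Default 50,000.
#' @param dilution_factor fold-dilution of the homogenate before
#'   acquisition (default 150).
#' @param sample_mass grams of feces per tube (default 0.1 g, i.e. 100 mg).
#' @param n_contaminants ASVs in the contaminant pool. The pool is disjoint
#'   from the community by default so control-based removal is unambiguous
#'   at truth level; set `contaminant_overlap = TRUE` for stress tests in
#'   which contaminants are community members.
#' @param contaminant_overlap see above.
#' @param load_sdlog log-scale SD of between-subject total load.
#' @param comp_concentration Dirichlet-like concentration controlling how
#'   far a subject's bulk composition scatters around the cohort baseline.
#' @param copula probability in `[0,1]` that an event's IgM and IgG states
#'   share a latent uniform, inducing IgM/IgG co-coating; default 0
#'   (independent isotypes).
#' @param seed integer seed; mandatory (every simulation is a pure function
#'   of `(config, seed)`).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 16,
                          n_asvs = 400,
                          mean_load = 2e10,
                          coating_prob_priors = list(iga = c(2, 8),
                                                     igm = c(2, 20),
                                                     igg = c(1.5, 15)),
                          category_probs = c(shared = 0.174,
                                             iga_only = 0.155,
                                             igm_only = 0.155,
                                             non_coated = 0.516),
                          iga_deficient_isotype_shift = list(igm = 0.25,
                                                             igg = 0.05),
                          igg_coating_prob = 0.3,
                          seq_depth = 20000,
                          contamination_rate = 0.02,
                          sort_purity = 0.95,
                          beads_added = 1e5,
                          n_events = 50000,
                          dilution_factor = 150,
                          sample_mass = 0.1,
                          n_contaminants = 12,
                          contaminant_overlap = FALSE,
                          load_sdlog = 0.35,
                          comp_concentration = 300,
                          copula = 0,
                          seed) {
  if (missing(seed)) stop("configuration error: 'seed' is mandatory")
  check_positive(seed, "seed", integer = TRUE)
  check_positive(n_pairs, "n_pairs", integer = TRUE)
  check_positive(n_asvs, "n_asvs", integer = TRUE)
  check_positive(mean_load, "mean_load")
  for (iso in c("iga", "igm", "igg")) {
    pr <- coating_prob_priors[[iso]]
    if (is.null(pr) || length(pr) != 2 || any(pr <= 0))
      stop("configuration error: 'coating_prob_priors$", iso,
           "' must be two positive Beta parameters")
  }
  if (length(category_probs) != 4 ||
      !setequal(names(category_probs),
                c("shared", "iga_only", "igm_only", "non_coated")) ||
      any(category_probs < 0) || abs(sum(category_probs) - 1) > 1e-8)
    stop("configuration error: 'category_probs' must be 4 named ",
         "probabilities summing to 1")
  check_prob(iga_deficient_isotype_shift$igm %||% NA,
             "iga_deficient_isotype_shift$igm")
  check_prob(iga_deficient_isotype_shift$igg %||% NA,
             "iga_deficient_isotype_shift$igg")
  check_prob(igg_coating_prob, "igg_coating_prob")
  check_nonneg(seq_depth, "seq_depth")
  check_prob(contamination_rate, "contamination_rate")
  check_prob(sort_purity, "sort_purity")
  if (sort_purity + contamination_rate > 1)
    stop("configuration error: 'sort_purity' + 'contamination_rate' ",
         "must not exceed 1")
  check_positive(beads_added, "beads_added")
  check_positive(n_events, "n_events", integer = TRUE)
  check_positive(dilution_factor, "dilution_factor")
  check_positive(sample_mass, "sample_mass")
  check_positive(n_contaminants, "n_contaminants", integer = TRUE)
  check_positive(load_sdlog, "load_sdlog")
  check_positive(comp_concentration, "comp_concentration")
  check_prob(copula, "copula")
  structure(as.list(environment()), class = "cohort_config")
}

# Deterministic child seed for the i-th internal simulation.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i) %% 2147483647L)
}

supported_sort_fractions <- function() {
  c("any_IgA_coated", "any_IgM_coated", "single_IgA", "double_IgAIgG",
    "single_IgM", "double_IgMIgG", "single_IgG", "non_coated")
}

# P(event falls in the gate of `fraction`) given per-ASV isotype
# probabilities pa/pm/pg (vectors).
gate_probability <- function(fraction, pa, pm, pg) {
  switch(fraction,
         any_IgA_coated = pa,
         any_IgM_coated = pm,
         single_IgA = pa * (1 - pm) * (1 - pg),
         double_IgAIgG = pa * pg * (1 - pm),
         single_IgM = pm * (1 - pa) * (1 - pg),
         double_IgMIgG = pm * pg * (1 - pa),
         single_IgG = pg * (1 - pa) * (1 - pm),
         non_coated = (1 - pa) * (1 - pm) * (1 - pg),
         stop("unknown fraction '", fraction, "'; supported: ",
              paste(supported_sort_fractions(), collapse = ", ")))
}

#' Per-ASV isotype coating probabilities for one IgA status
#'
#' Shared and IgA-only ASVs are IgA-coated in IgA+ subjects; in IgA-
#' subjects IgA coating is exactly zero and, for shared ASVs, part of the
#' IgA coating probability reappears as IgM (and extra IgG) per the
#' configured isotype shift. IgM-only ASVs are coated only in IgA-
#' subjects.
#'
#' @param truth a `cohort_truth` object.
#' @param iga_status `"IgA+"` or `"IgA-"`.
#' @return matrix (ASV x isotype) with columns `iga`, `igm`, `igg`.
#' @export
coating_prob_matrix <- function(truth, iga_status) {
  stopifnot(inherits(truth, "cohort_truth"),
            iga_status %in% c("IgA+", "IgA-"))
  tx <- truth$asvs
  shift <- truth$config$iga_deficient_isotype_shift
  pa <- pm <- numeric(nrow(tx))
  pg <- tx$p_igg
  if (iga_status == "IgA+") {
    sel <- tx$category %in% c("shared", "iga_only")
    pa[sel] <- tx$p_coat[sel]
  } else {
    pm[tx$category == "igm_only"] <- tx$p_coat[tx$category == "igm_only"]
    sh <- tx$category == "shared"
    pm[sh] <- pmin(1, shift$igm * tx$p_coat[sh])
    pg[sh] <- pmin(1, pg[sh] + shift$igg * tx$p_coat[sh])
  }
  m <- cbind(iga = pa, igm = pm, igg = pg)
  rownames(m) <- tx$asv_id
  m
}

#' Generate the latent ground truth of a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort_truth`: `asvs` (taxonomy, true category,
#'   coating probabilities, 16S-like tag sequence), `subjects` (pairing,
#'   IgA status, true total load), `bulk_comp` (ASV x subject bulk
#'   relative abundances), `contaminants` (pool ids, taxonomy and
#'   composition), `ko_profiles` (long `taxon_id`/`ko` table) and the
#'   config itself.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cat_tbl <- gut_family_catalog()

  n <- config$n_asvs
  fam_idx <- sample.int(nrow(cat_tbl), n, replace = TRUE,
                        prob = cat_tbl$asv_weight)
  # guarantee an E. coli-like Enterobacteriaceae taxon
  if (!any(cat_tbl$family[fam_idx] == "Enterobacteriaceae"))
    fam_idx[1] <- which(cat_tbl$family == "Enterobacteriaceae")
  asv_id <- sprintf("ASV%04d", seq_len(n))
  family <- cat_tbl$family[fam_idx]
  phylum <- cat_tbl$phylum[fam_idx]

  # baseline composition: family mass split log-normally across members
  w <- stats::rlnorm(n, 0, 1)
  base_comp <- numeric(n)
  for (f in unique(family)) {
    sel <- family == f
    base_comp[sel] <- w[sel] / sum(w[sel]) *
      cat_tbl$mean_abundance[match(f, cat_tbl$family)]
  }
  base_comp <- base_comp / sum(base_comp)

  species <- rep(NA_character_, n)
  entero <- which(family == "Enterobacteriaceae")
  species[entero[which.max(base_comp[entero])]] <- "Escherichia coli"

  category <- sample(names(config$category_probs), n, replace = TRUE,
                     prob = config$category_probs)
  p_coat <- numeric(n)
  pri <- config$coating_prob_priors
  sel_a <- category %in% c("shared", "iga_only")
  p_coat[sel_a] <- stats::rbeta(sum(sel_a), pri$iga[1], pri$iga[2])
  sel_m <- category == "igm_only"
  p_coat[sel_m] <- stats::rbeta(sum(sel_m), pri$igm[1], pri$igm[2])
  p_igg <- numeric(n)
  coated <- category != "non_coated"
  has_igg <- coated & stats::runif(n) < config$igg_coating_prob
  p_igg[has_igg] <- stats::rbeta(sum(has_igg), pri$igg[1], pri$igg[2])

  bases <- c("A", "C", "G", "T")
  sequence <- vapply(seq_len(n), function(i)
    paste(sample(bases, 120, replace = TRUE), collapse = ""), character(1))

  asvs <- data.frame(asv_id = asv_id, phylum = phylum, family = family,
                     species = species, category = category,
                     p_coat = p_coat, p_igg = p_igg,
                     base_abundance = base_comp, sequence = sequence,
                     stringsAsFactors = FALSE)

  subjects <- data.frame(
    subject_id = paste0("S", rep(seq_len(config$n_pairs), each = 2),
                        rep(c("P", "D"), config$n_pairs)),
    pair_id = paste0("H", rep(seq_len(config$n_pairs), each = 2)),
    iga_status = rep(c("IgA+", "IgA-"), config$n_pairs),
    stringsAsFactors = FALSE)
  subjects$true_load <- stats::rlnorm(
    nrow(subjects),
    log(config$mean_load), config$load_sdlog)

  conc <- config$comp_concentration
  bulk_comp <- vapply(seq_len(nrow(subjects)), function(i) {
    g <- stats::rgamma(n, shape = base_comp * conc)
    if (sum(g) == 0) g <- base_comp
    g / sum(g)
  }, numeric(n))
  dimnames(bulk_comp) <- list(asv_id, subjects$subject_id)

  # contaminant pool (reagent-style taxa), disjoint by default
  if (config$contaminant_overlap) {
    pool_ids <- sample(asv_id, config$n_contaminants)
    pool_tax <- asvs[match(pool_ids, asvs$asv_id),
                     c("asv_id", "phylum", "family")]
  } else {
    pool_ids <- sprintf("CONTAM%02d", seq_len(config$n_contaminants))
    pf <- sample.int(nrow(cat_tbl), config$n_contaminants, replace = TRUE)
    pool_tax <- data.frame(asv_id = pool_ids, phylum = cat_tbl$phylum[pf],
                           family = cat_tbl$family[pf],
                           stringsAsFactors = FALSE)
  }
  pool_comp <- stats::rgamma(config$n_contaminants, shape = 2)
  pool_comp <- pool_comp / sum(pool_comp)
  pool_seq <- vapply(seq_len(config$n_contaminants), function(i)
    paste(sample(bases, 120, replace = TRUE), collapse = ""), character(1))

  ko_profiles <- simulate_ko_profiles(asvs)

  structure(list(config = config, asvs = asvs, subjects = subjects,
                 bulk_comp = bulk_comp,
                 contaminants = list(ids = pool_ids, taxonomy = pool_tax,
                                     composition = pool_comp,
                                     sequence = pool_seq),
                 ko_profiles = ko_profiles),
            class = "cohort_truth")
}

# Build per-taxon KO sets consistent with the default ligand rules:
# carriers within capability-bearing families receive a complete KO
# requirement set, non-carriers an incomplete one. Uses the shipped rule
# table so capability calls on the truth are exact by construction.
simulate_ko_profiles <- function(asvs) {
  rules <- load_ligand_rules()
  capfam <- capability_families()
  complete_kos <- function(cap) {
    kos <- unlist(lapply(cap$groups, `[`, 1))
    if (length(cap$routes)) kos <- c(kos, unlist(lapply(cap$routes[[1]],
                                                        `[`, 1)))
    unique(kos)
  }
  out <- vector("list", nrow(asvs))
  for (i in seq_len(nrow(asvs))) {
    fam <- asvs$family[i]
    kos <- character(0)
    if (fam %in% capfam$flagellin && stats::runif(1) < 0.4)
      kos <- c(kos, complete_kos(rules$flagellin))
    if (fam %in% capfam$lps) {
      kos <- c(kos, complete_kos(rules$lps_core))
      if (fam %in% capfam$lps_hexa && stats::runif(1) < 0.5)
        kos <- c(kos, complete_kos(rules$lps_hexa_extension))
    }
    if (fam %in% capfam$butyrate && stats::runif(1) < 0.5) {
      kos <- c(kos, complete_kos(rules$butyrate))
    } else if (fam %in% capfam$butyrate) {
      # incomplete route: terminal group present, route broken
      kos <- c(kos, rules$butyrate$groups[[1]][1])
    }
    # decoy KOs outside every rule
    kos <- c(kos, sprintf("K%05d", sample(70000:79999, 2)))
    out[[i]] <- data.frame(taxon_id = asvs$asv_id[i], ko = unique(kos),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate one bead-spiked flow-cytometry acquisition
#'
#' Events are cells or counting beads. The expected cell:bead event ratio
#' is the inversion of the bead calibration formula, so
#' [absolute_load()] applied to the simulated acquisition recovers
#' `true_load` in expectation. Each cell draws one Boolean coating state
#' per isotype (independent Bernoulli by default; `copula` induces IgM/IgG
#' co-coating) and channel intensities come from two log-normal components
#' (negative / positive), so thresholding the intensities recovers the
#' drawn state exactly.
#'
#' @param true_load true total bacteria per gram.
#' @param coating_probs named per-isotype coating probabilities, e.g.
#'   `c(iga = .08, igm = 0, igg = .02)`; names become channel columns.
#' @param n_events total recorded events (cells + beads).
#' @param beads_added beads spiked into the tube.
#' @param dilution_factor,sample_mass acquisition geometry, as in
#'   [absolute_load()].
#' @param copula probability that IgM and IgG states share a latent
#'   uniform (requires both channels present).
#' @param seed integer seed.
#' @return event `data.frame` with `event_id`, `dapi`, one column per
#'   isotype, `is_bead`; attribute `states` holds the drawn Boolean states
#'   for validation.
#' @export
simulate_flow_events <- function(true_load, coating_probs, n_events,
                                 beads_added, dilution_factor = 150,
                                 sample_mass = 0.1, copula = 0, seed) {
  if (missing(seed)) stop("configuration error: 'seed' is mandatory")
  check_positive(true_load, "true_load")
  check_positive(n_events, "n_events", integer = TRUE)
  check_positive(beads_added, "beads_added")
  for (nm in names(coating_probs)) check_prob(coating_probs[[nm]], nm)
  check_prob(copula, "copula")
  set.seed(seed)

  r <- true_load * sample_mass / (dilution_factor * beads_added)
  p_bead <- 1 / (1 + r)
  n_beads <- stats::rbinom(1, n_events, p_bead)
  n_cells <- n_events - n_beads

  channels <- names(coating_probs)
  states <- matrix(FALSE, n_cells, length(channels),
                   dimnames = list(NULL, channels))
  u <- matrix(stats::runif(n_cells * length(channels)), n_cells)
  if (copula > 0 && all(c("igm", "igg") %in% channels)) {
    share <- stats::runif(n_cells) < copula
    u[share, match("igg", channels)] <- u[share, match("igm", channels)]
  }
  for (j in seq_along(channels))
    states[, j] <- u[, j] < coating_probs[[channels[j]]]

  intensity <- function(state) {
    stats::rlnorm(length(state),
                  meanlog = ifelse(state, log(5000), log(30)),
                  sdlog = 0.5)
  }
  ev <- data.frame(event_id = seq_len(n_events))
  bead_flag <- c(rep(FALSE, n_cells), rep(TRUE, n_beads))
  ev$dapi <- intensity(c(rep(TRUE, n_cells), rep(TRUE, n_beads)))
  for (j in seq_along(channels))
    ev[[channels[j]]] <- intensity(c(states[, j], rep(FALSE, n_beads)))
  ev$is_bead <- bead_flag
  # shuffle so acquisition order carries no information
  ord <- sample.int(n_events)
  ev <- ev[ord, , drop = FALSE]
  ev$event_id <- seq_len(n_events)
  rownames(ev) <- NULL
  attr(ev, "states") <- states
  ev
}

#' Simulate an FMO control acquisition (negative component only)
#'
#' @param n_events events to draw.
#' @param channels isotype channel names.
#' @param seed integer seed.
#' @return event `data.frame` with all isotype channels drawn from the
#'   negative log-normal component.
#' @export
simulate_fmo_events <- function(n_events, channels = c("iga", "igm", "igg"),
                                seed) {
  if (missing(seed)) stop("configuration error: 'seed' is mandatory")
  set.seed(seed)
  ev <- data.frame(event_id = seq_len(n_events))
  ev$dapi <- stats::rlnorm(n_events, log(5000), 0.5)
  for (ch in channels)
    ev[[ch]] <- stats::rlnorm(n_events, log(30), 0.5)
  ev$is_bead <- FALSE
  ev
}

#' Simulate the read counts of one FACS-sorted sample
#'
#' Reads are a single multinomial draw of `depth` reads whose source
#' distribution mixes (i) the true gated composition of the fraction with
#' weight `sort_purity`, (ii) carry-over of the subject's bulk community
#' with weight `1 - sort_purity - contamination_rate`, and (iii) the
#' contaminant pool (the same pool emitted into negative controls) with
#' weight `contamination_rate`.
#'
#' @param truth a `cohort_truth`.
#' @param subject_id one of `truth$subjects$subject_id`.
#' @param fraction_def gate name, one of the supported sort fractions.
#' @param depth reads to draw (0 gives an all-zero vector).
#' @param contamination_rate,sort_purity override the config values
#'   (defaults taken from `truth$config`).
#' @param seed integer seed.
#' @return named integer count vector over community + contaminant ASVs.
#' @export
simulate_sorted_counts <- function(truth, subject_id, fraction_def, depth,
                                   contamination_rate = NULL,
                                   sort_purity = NULL, seed) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (missing(seed)) stop("configuration error: 'seed' is mandatory")
  if (!fraction_def %in% c(supported_sort_fractions(), "bulk"))
    stop("unknown fraction '", fraction_def, "'; supported: ",
         paste(c(supported_sort_fractions(), "bulk"), collapse = ", "))
  si <- match(subject_id, truth$subjects$subject_id)
  if (is.na(si)) stop("unknown subject '", subject_id, "'")
  contamination_rate <- contamination_rate %||%
    truth$config$contamination_rate
  sort_purity <- sort_purity %||% truth$config$sort_purity
  set.seed(seed)

  bulk <- truth$bulk_comp[, si]
  if (fraction_def == "bulk") {
    target <- bulk
    purity <- 1 - contamination_rate
  } else {
    pm <- coating_prob_matrix(truth, truth$subjects$iga_status[si])
    gate <- gate_probability(fraction_def, pm[, "iga"], pm[, "igm"],
                             pm[, "igg"])
    mass <- bulk * gate
    target <- if (sum(mass) > 0) mass / sum(mass) else mass
    purity <- sort_purity
  }
  carry <- max(0, 1 - purity - contamination_rate)
  n_comm <- nrow(truth$asvs)
  probs <- c(purity * target + carry * bulk,
             contamination_rate * truth$contaminants$composition)
  names(probs) <- c(truth$asvs$asv_id, truth$contaminants$ids)
  if (truth$config$contaminant_overlap) {
    # overlap mode: contaminant mass lands on community ASV entries
    idx <- match(truth$contaminants$ids, truth$asvs$asv_id)
    comm <- probs[seq_len(n_comm)]
    comm[idx] <- comm[idx] + probs[n_comm + seq_along(idx)]
    probs <- comm
  }
  if (depth == 0 || sum(probs) == 0)
    return(stats::setNames(integer(length(probs)), names(probs)))
  as.integer(stats::rmultinom(1, depth, probs))[seq_along(probs)] |>
    stats::setNames(names(probs))
}

#' Generate a full synthetic cohort and raw-input bundle
#'
#' For every household pair this emits, per subject: a bead-spiked
#' multi-isotype flow event table, the FACS-sorted fraction set (any-IgA,
#' single-IgA and double-IgAIgG for the IgA+ member; any-IgM, single-IgM
#' and double-IgMIgG for the IgA- member; non-coated for both), and a bulk
#' sample — plus three shared negative controls (pre-sort fluid,
#' extraction blank, PCR blank) fed from the contaminant pool, an FMO
#' acquisition, and the per-taxon KO profiles. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return list with `truth` (see [generate_ground_truth()]) and `bundle`:
#'   `counts` (a [sorted_counts()] with every sorted/bulk/control sample),
#'   `events` (named list of per-subject event tables), `fmo_events`,
#'   `flow_meta` (per-subject acquisition geometry) and `ko_profiles`.
#' @export
generate_cohort <- function(config) {
  truth <- generate_ground_truth(config)
  subjects <- truth$subjects
  ctr <- 0L
  nxt <- function() {
    ctr <<- ctr + 1L
    child_seed(config$seed, ctr)
  }

  events <- list()
  sample_counts <- list()
  meta_rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    status <- subjects$iga_status[i]
    pmat <- coating_prob_matrix(truth, status)
    marg <- colSums(truth$bulk_comp[, i] * pmat)
    events[[sid]] <- simulate_flow_events(
      true_load = subjects$true_load[i], coating_probs = marg,
      n_events = config$n_events, beads_added = config$beads_added,
      dilution_factor = config$dilution_factor,
      sample_mass = config$sample_mass, copula = config$copula,
      seed = nxt())
    fracs <- if (status == "IgA+")
      c("any_IgA_coated", "single_IgA", "double_IgAIgG", "non_coated")
    else
      c("any_IgM_coated", "single_IgM", "double_IgMIgG", "non_coated")
    for (fr in c(fracs, "bulk")) {
      sample_id <- paste(sid, fr, sep = ".")
      sample_counts[[sample_id]] <- simulate_sorted_counts(
        truth, sid, fr, depth = config$seq_depth, seed = nxt())
      meta_rows[[sample_id]] <- data.frame(
        sample_id = sample_id, subject_id = sid,
        pair_id = subjects$pair_id[i], iga_status = status,
        fraction_type = fr, stringsAsFactors = FALSE)
    }
  }

  # shared negative controls drawn from the contaminant pool
  ctrl_depth <- round(config$seq_depth * config$contamination_rate)
  all_ids <- names(sample_counts[[1]])
  pool_idx <- match(if (config$contaminant_overlap)
    truth$contaminants$ids else truth$contaminants$ids, all_ids)
  for (ct in control_fraction_types()) {
    v <- stats::setNames(integer(length(all_ids)), all_ids)
    if (ctrl_depth > 0 && config$contamination_rate > 0) {
      set.seed(nxt())
      draw <- stats::rmultinom(1, ctrl_depth,
                               truth$contaminants$composition)[, 1]
      v[pool_idx] <- v[pool_idx] + as.integer(draw)
    }
    sample_counts[[ct]] <- v
    meta_rows[[ct]] <- data.frame(
      sample_id = ct, subject_id = NA_character_, pair_id = NA_character_,
      iga_status = NA_character_, fraction_type = ct,
      stringsAsFactors = FALSE)
  }

  counts <- do.call(cbind, sample_counts)
  meta <- do.call(rbind, meta_rows)
  taxonomy <- rbind(
    truth$asvs[, c("asv_id", "phylum", "family", "species")],
    cbind(truth$contaminants$taxonomy[
      !truth$contaminants$taxonomy$asv_id %in% truth$asvs$asv_id, ,
      drop = FALSE], species = NA_character_))
  table <- sorted_counts(counts, meta, taxonomy)

  fmo <- simulate_fmo_events(5000, c("iga", "igm", "igg"), seed = nxt())
  flow_meta <- data.frame(
    subject_id = subjects$subject_id,
    beads_added = config$beads_added,
    dilution_factor = config$dilution_factor,
    sample_mass = config$sample_mass, stringsAsFactors = FALSE)

  list(truth = truth,
       bundle = list(counts = table, events = events, fmo_events = fmo,
                     flow_meta = flow_meta,
                     ko_profiles = truth$ko_profiles))
}

#' True cohort-level coating category of each community ASV
#'
#' @param truth a `cohort_truth`.
#' @return data.frame `asv_id`, `true_category` with levels
#'   `shared`, `iga_only` (coated in IgA+ only), `igm_only`, `non_coated`.
#' @export
true_categories <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  data.frame(asv_id = truth$asvs$asv_id,
             true_category = truth$asvs$category,
             stringsAsFactors = FALSE)
}

#' Expected sorted-read counts of each ASV in its defining gates
#'
#' Used to restrict recovery checks to detectable ASVs: for each community
#' ASV, the maximum (over subjects of the relevant status) expected number
#' of reads in the any-IgA gate, the any-IgM gate, and the non-coated
#' gate, at the given depth and purity with no contamination.
#'
#' @param truth a `cohort_truth`.
#' @param depth reads per sample.
#' @param sort_purity purity used in the expectation.
#' @return data.frame `asv_id`, `exp_any_iga`, `exp_any_igm`,
#'   `exp_non_coated`.
#' @export
expected_gate_reads <- function(truth, depth = truth$config$seq_depth,
                                sort_purity = truth$config$sort_purity) {
  stopifnot(inherits(truth, "cohort_truth"))
  res <- data.frame(asv_id = truth$asvs$asv_id,
                    exp_any_iga = 0, exp_any_igm = 0, exp_non_coated = 0)
  for (status in c("IgA+", "IgA-")) {
    pm <- coating_prob_matrix(truth, status)
    subj <- which(truth$subjects$iga_status == status)
    frs <- if (status == "IgA+") c(iga = "any_IgA_coated") else
      c(igm = "any_IgM_coated")
    for (i in subj) {
      bulk <- truth$bulk_comp[, i]
      for (nm in names(frs)) {
        g <- gate_probability(frs[[nm]], pm[, "iga"], pm[, "igm"],
                              pm[, "igg"])
        mass <- bulk * g
        if (sum(mass) > 0) {
          e <- depth * sort_purity * mass / sum(mass)
          col <- paste0("exp_any_", nm)
          res[[col]] <- pmax(res[[col]], e)
        }
      }
      gnc <- gate_probability("non_coated", pm[, "iga"], pm[, "igm"],
                              pm[, "igg"])
      mass <- bulk * gnc
      if (sum(mass) > 0)
        res$exp_non_coated <- pmax(res$exp_non_coated,
                                   depth * sort_purity * mass / sum(mass))
    }
  }
  res
}

#' Write a cohort bundle to plain-text files
#'
#' Emits per-subject event CSVs, the FMO CSV, count/metadata/taxonomy
#' TSVs, ASV sequences as FASTA, KO profiles as TSV and the ground truth
#' as JSON under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  evdir <- file.path(dir, "events")
  dir.create(evdir, showWarnings = FALSE)
  for (sid in names(cohort$bundle$events))
    utils::write.csv(cohort$bundle$events[[sid]],
                     file.path(evdir, paste0(sid, ".csv")),
                     row.names = FALSE)
  utils::write.csv(cohort$bundle$fmo_events, file.path(dir, "fmo.csv"),
                   row.names = FALSE)
  write_sorted_counts(cohort$bundle$counts, dir)
  utils::write.table(cohort$bundle$ko_profiles,
                     file.path(dir, "ko_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seqs <- c(stats::setNames(cohort$truth$asvs$sequence,
                            cohort$truth$asvs$asv_id),
            stats::setNames(cohort$truth$contaminants$sequence,
                            cohort$truth$contaminants$ids))
  writeLines(paste0(">", names(seqs), "\n", seqs),
             file.path(dir, "asvs.fasta"))
  truth_json <- cohort$truth
  truth_json$config <- unclass(truth_json$config)
  truth_json$bulk_comp <- as.data.frame(truth_json$bulk_comp)
  jsonlite::write_json(unclass(truth_json),
                       file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
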