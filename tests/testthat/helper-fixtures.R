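# Small programmatic fixtures shared across test files.

toy_taxonomy <- function(asv_ids, family = "Lachnospiraceae",
                         phylum = "Firmicutes") {
  data.frame(asv_id = asv_ids,
             phylum = rep_len(phylum, length(asv_ids)),
             family = rep_len(family, length(asv_ids)),
             stringsAsFactors = FALSE)
}

# A 4-ASV table with one household pair, bulk samples and the three
# controls; ASV3 contaminates the PCR control.
toy_sorted_table <- function(asv3_in_pcr = 10) {
  asvs <- paste0("ASV", 1:4)
  samples <- c("p.coated", "p.non", "p.bulk",
               "d.coated", "d.non", "d.bulk",
               "presort", "blank", "pcr")
  counts <- matrix(0L, 4, length(samples),
                   dimnames = list(asvs, samples))
  counts["ASV1", ] <- c(50, 0, 40, 0, 5, 35, 0, 0, 0)
  counts["ASV2", ] <- c(0, 60, 30, 45, 0, 30, 0, 0, 0)
  counts["ASV3", ] <- c(5, 5, 20, 5, 5, 20, 0, 0, asv3_in_pcr)
  counts["ASV4", ] <- c(10, 0, 10, 12, 0, 15, 0, 0, 0)
  meta <- data.frame(
    sample_id = samples,
    subject_id = c(rep("S1P", 3), rep("S1D", 3), rep(NA, 3)),
    pair_id = c(rep("H1", 6), rep(NA, 3)),
    iga_status = c(rep("IgA+", 3), rep("IgA-", 3), rep(NA, 3)),
    fraction_type = c("any_IgA_coated", "non_coated", "bulk",
                      "any_IgM_coated", "non_coated", "bulk",
                      "control_presort", "control_blank", "control_pcr"),
    stringsAsFactors = FALSE)
  sorted_counts(counts, meta, toy_taxonomy(asvs))
}

# Event table whose classification can be enumerated by hand. Thresholds
# of 100 on each of three channels; 6 events with known combinations.
toy_events <- function() {
  data.frame(
    event_id = 1:6,
    dapi = rep(5000, 6),
    iga = c(500, 500,  50, 500,  50,  50),
    igm = c(500,  50,  50, 500, 500,  50),
    igg = c(500,  50, 500,  50,  50,  50),
    is_bead = FALSE)
}

toy_thresholds <- function() {
  structure(c(iga = 100, igm = 100, igg = 100),
            quantile = 0.999, class = "gate_thresholds")
}

# Presence table covering every combination of presence bits over the
# classes (any coated, single coated, non-coated) x (IgA+, IgA-): one ASV
# per pattern, counts equal to the bits.
enumerated_presence_table <- function() {
  combos <- expand.grid(rep(list(c(0L, 1L)), 6))
  names(combos) <- c("anyA", "singleA", "ncP", "anyM", "singleM", "ncD")
  asvs <- sprintf("P%02d", seq_len(nrow(combos)))
  samples <- c("S1P.any", "S1P.single", "S1P.nc",
               "S1D.any", "S1D.single", "S1D.nc")
  counts <- as.matrix(combos)
  dimnames(counts) <- list(asvs, samples)
  meta <- data.frame(
    sample_id = samples,
    subject_id = rep(c("S1P", "S1D"), each = 3),
    pair_id = "H1",
    iga_status = rep(c("IgA+", "IgA-"), each = 3),
    fraction_type = c("any_IgA_coated", "single_IgA", "non_coated",
                      "any_IgM_coated", "single_IgM", "non_coated"),
    stringsAsFactors = FALSE)
  list(table = sorted_counts(counts, meta, toy_taxonomy(asvs)),
       combos = combos)
}

# A tiny, fast synthetic cohort for pipeline-level tests.
small_cohort_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_pairs = 3, n_asvs = 80, seq_depth = 5000, n_events = 10000,
         seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# Thresholds sitting in the gap between the simulator's negative and
# positive intensity components (log-normal around 30 and 5000).
sep_thresholds <- function(channels = c("iga", "igm", "igg")) {
  structure(setNames(rep(300, length(channels)), channels),
            class = "gate_thresholds")
}
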