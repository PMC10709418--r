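test_that("configuration validation names the offending field", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(n_pairs = 0, seed = 1), "n_pairs")
  expect_error(cohort_config(contamination_rate = 1.2, seed = 1),
               "contamination_rate")
  expect_error(cohort_config(sort_purity = 0.9, contamination_rate = 0.2,
                             seed = 1), "sort_purity")
  expect_error(cohort_config(coating_prob_priors = list(iga = c(2, 8)),
                             seed = 1), "igm")
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- small_cohort_config(seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth$asvs, b$truth$asvs)
  expect_identical(a$bundle$counts$counts, b$bundle$counts$counts)
  expect_identical(a$bundle$events, b$bundle$events)
  c <- generate_cohort(small_cohort_config(seed = 78))
  expect_false(identical(a$bundle$counts$counts, c$bundle$counts$counts))
})

test_that("cohort structure matches the paired sort-seq design", {
  cfg <- small_cohort_config(seed = 5)
  co <- generate_cohort(cfg)
  meta <- co$bundle$counts$meta
  # each pair has exactly one IgA+ and one IgA- subject
  subj <- unique(meta[!is.na(meta$subject_id),
                      c("subject_id", "pair_id", "iga_status")])
  tab <- table(subj$pair_id, subj$iga_status)
  expect_true(all(tab == 1))
  # IgA+ subjects carry IgA-based sorts, IgA- subjects IgM-based
  plus <- meta$fraction_type[meta$iga_status %in% "IgA+"]
  expect_true(all(c("any_IgA_coated", "single_IgA", "double_IgAIgG",
                    "non_coated", "bulk") %in% plus))
  expect_false("any_IgM_coated" %in% plus)
  # three shared controls
  expect_equal(sum(is_control_sample(co$bundle$counts)), 3)
  # read conservation: every sorted/bulk sample sums to the depth
  noncontrol <- !is_control_sample(co$bundle$counts)
  expect_true(all(colSums(co$bundle$counts$counts[, noncontrol]) ==
                    cfg$seq_depth))
})

test_that("controls are empty without contamination and filled from the pool", {
  clean <- generate_cohort(small_cohort_config(seed = 9,
                                               contamination_rate = 0))
  ctrl <- is_control_sample(clean$bundle$counts)
  expect_true(all(clean$bundle$counts$counts[, ctrl] == 0))
  # IgA coating truly absent in IgA- subjects
  pm <- coating_prob_matrix(clean$truth, "IgA-")
  expect_true(all(pm[, "iga"] == 0))

  dirty <- generate_cohort(small_cohort_config(seed = 9,
                                               contamination_rate = 0.05))
  dctrl <- dirty$bundle$counts$counts[, is_control_sample(dirty$bundle$counts)]
  expect_gt(sum(dctrl), 0)
  # control reads land only on the contaminant pool
  on_pool <- rownames(dctrl) %in% dirty$truth$contaminants$ids
  expect_true(all(dctrl[!on_pool, ] == 0))
})

test_that("doubling the sequencing depth doubles per-sample reads", {
  co1 <- generate_cohort(small_cohort_config(seed = 21, seq_depth = 4000))
  co2 <- generate_cohort(small_cohort_config(seed = 21, seq_depth = 8000))
  nc1 <- !is_control_sample(co1$bundle$counts)
  nc2 <- !is_control_sample(co2$bundle$counts)
  expect_equal(colSums(co2$bundle$counts$counts[, nc2]),
               2 * colSums(co1$bundle$counts$counts[, nc1]))
})

test_that("flow events encode the drawn coating states and bead ratio", {
  # all-zero probabilities: every non-bead event is all-negative
  ev0 <- simulate_flow_events(2e10, c(iga = 0, igm = 0, igg = 0),
                              n_events = 5000, beads_added = 1e5,
                              seed = 31)
  prof0 <- classify_events(ev0, sep_thresholds())
  expect_equal(prof0$counts[["none"]], prof0$n_gated)

  # certain IgA coating: every cell is IgA+
  ev1 <- simulate_flow_events(2e10, c(iga = 1, igm = 0, igg = 0),
                              n_events = 5000, beads_added = 1e5,
                              seed = 32)
  prof1 <- classify_events(ev1, sep_thresholds())
  expect_equal(marginal_count(prof1, "iga"), prof1$n_gated)

  # doubling the true load doubles the cell:bead event ratio
  ratios <- sapply(1:10, function(s) {
    e1 <- simulate_flow_events(1e10, c(iga = 0.1), 50000, 1e5, seed = 40 + s)
    e2 <- simulate_flow_events(2e10, c(iga = 0.1), 50000, 1e5,
                               seed = 140 + s)
    r <- function(e) sum(!e$is_bead) / sum(e$is_bead)
    r(e2) / r(e1)
  })
  expect_lt(abs(mean(ratios) - 2), 0.15)
})

test_that("sorted counts follow the purity/contamination mixture", {
  cfg <- small_cohort_config(seed = 55, contamination_rate = 0)
  truth <- generate_ground_truth(cfg)
  sid <- truth$subjects$subject_id[1]

  expect_error(simulate_sorted_counts(truth, sid, "nonsense", 100,
                                      seed = 1), "supported")
  zero <- simulate_sorted_counts(truth, sid, "any_IgA_coated", 0, seed = 1)
  expect_true(all(zero == 0))

  # single fully-coated ASV under a pure sort takes every read
  mono <- truth
  mono$asvs$category <- c("iga_only", rep("non_coated",
                                          nrow(mono$asvs) - 1))
  mono$asvs$p_coat <- c(1, rep(0, nrow(mono$asvs) - 1))
  mono$asvs$p_igg <- 0
  v <- simulate_sorted_counts(mono, sid, "any_IgA_coated", 5000,
                              contamination_rate = 0, sort_purity = 1,
                              seed = 2)
  expect_equal(unname(v[mono$asvs$asv_id[1]]), 5000L)

  # two equal-mass coated ASVs split reads evenly (binomial oracle)
  duo <- mono
  duo$asvs$category[2] <- "iga_only"
  duo$asvs$p_coat[2] <- 1
  duo$bulk_comp[, 1] <- 0
  duo$bulk_comp[1:2, 1] <- 0.5
  v2 <- simulate_sorted_counts(duo, sid, "any_IgA_coated", 10000,
                               contamination_rate = 0, sort_purity = 1,
                               seed = 3)
  share <- v2[[1]] / 10000
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("a written bundle round-trips through plain-text files", {
  co <- generate_cohort(cohort_config(n_pairs = 2, n_asvs = 30,
                                      seq_depth = 1000, n_events = 2000,
                                      seed = 12))
  dir <- withr::local_tempdir()
  write_cohort_bundle(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("counts.tsv", "samples.tsv", "taxonomy.tsv", "fmo.csv",
           "ko_profiles.tsv", "asvs.fasta", "ground_truth.json")))))
  back <- read_sorted_counts(dir)
  expect_equal(back$counts, co$bundle$counts$counts)
  # FASTA holds one record per ASV (community + contaminants)
  fa <- readLines(file.path(dir, "asvs.fasta"))
  expect_equal(sum(grepl("^>", fa)),
               nrow(co$truth$asvs) + length(co$truth$contaminants$ids))
})
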