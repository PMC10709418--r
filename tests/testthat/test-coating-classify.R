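test_that("presence matrix matches hand enumeration on a toy table", {
  tab <- toy_sorted_table(asv3_in_pcr = 0)
  pres <- presence_matrix(tab)
  arr <- pres$cohort
  expect_true(arr["ASV1", "any_IgA_coated", "IgA+"])
  expect_false(arr["ASV1", "any_IgM_coated", "IgA-"])
  expect_true(arr["ASV2", "non_coated", "IgA+"])
  expect_true(arr["ASV2", "any_IgM_coated", "IgA-"])
  expect_true(arr["ASV4", "any_IgA_coated", "IgA+"])
  # min_count raises the detection bar
  pres6 <- presence_matrix(tab, min_count = 6)
  expect_false(pres6$cohort["ASV3", "any_IgA_coated", "IgA+"])
})

test_that("category assignment agrees with the exhaustive truth-table oracle", {
  fix <- enumerated_presence_table()
  cls <- classify_asvs(presence_matrix(fix$table))
  got <- setNames(cls$category, cls$asv_id)
  for (i in seq_len(nrow(fix$combos))) {
    b <- fix$combos[i, ]
    want <- oracle_classify_bits(
      coated_plus = b$anyA == 1 || b$singleA == 1,
      coated_minus = b$anyM == 1 || b$singleM == 1,
      in_noncoated = b$ncP == 1 || b$ncD == 1)
    expect_identical(unname(got[sprintf("P%02d", i)]), want,
                     label = paste("pattern", i))
  }
})

test_that("the worked category examples classify as described", {
  fix <- enumerated_presence_table()
  cls <- classify_asvs(presence_matrix(fix$table))
  got <- setNames(cls$category, cls$asv_id)
  pattern_id <- function(anyA, singleA, ncP, anyM, singleM, ncD) {
    m <- fix$combos
    sprintf("P%02d", which(m$anyA == anyA & m$singleA == singleA &
                             m$ncP == ncP & m$anyM == anyM &
                             m$singleM == singleM & m$ncD == ncD))
  }
  # only in non-coated fractions of both subjects -> strictly non-coated
  expect_identical(unname(got[pattern_id(0, 0, 1, 0, 0, 1)]),
                   "strictly_non_coated")
  # IgA-coated in IgA+ and IgM-coated in IgA- -> shared
  expect_identical(unname(got[pattern_id(1, 0, 0, 1, 0, 0)]), "shared")
  # coated in one subject, non-coated fraction of the other -> coated wins
  expect_identical(unname(got[pattern_id(1, 0, 0, 0, 0, 1)]), "iga_only")
})

test_that("classification is invariant to sample order and duplicated samples", {
  tab <- toy_sorted_table(asv3_in_pcr = 0)
  base <- classify_asvs(presence_matrix(tab))
  perm <- subset_samples(tab, rev(seq_len(ncol(tab$counts))))
  expect_equal(classify_asvs(presence_matrix(perm)), base)
  dup <- tab
  extra <- tab$counts[, "p.coated", drop = FALSE]
  colnames(extra) <- "p.coated.rep"
  dup_counts <- cbind(tab$counts, extra)
  dup_meta <- rbind(tab$meta,
                    within(tab$meta[tab$meta$sample_id == "p.coated", ],
                           sample_id <- "p.coated.rep"))
  dup <- sorted_counts(dup_counts, dup_meta, tab$taxonomy)
  expect_equal(classify_asvs(presence_matrix(dup)), base)
})

test_that("category summaries count, rollup and round as printed", {
  cls <- data.frame(
    asv_id = paste0("A", 1:4),
    category = c("shared", "iga_only", "strictly_non_coated",
                 "unobserved"),
    phylum = c("Firmicutes", "Bacteroidetes", "Firmicutes", "Firmicutes"),
    family = c("Lachnospiraceae", "Bacteroidaceae", "Rikenellaceae",
               "Clostridiaceae"), stringsAsFactors = FALSE)
  s <- summarize_categories(cls)
  expect_equal(s$coated_total, 2)
  expect_equal(unname(s$category_pct["shared"]), 50)
  expect_equal(s$category_counts[["strictly_non_coated"]], 1)
  # one coated ASV -> 100% in its category
  one <- summarize_categories(cls[1, , drop = FALSE])
  expect_equal(unname(one$category_pct["shared"]), 100)
  # rounding convention: >= 10% integer, < 10% one decimal
  expect_equal(round_pct(c(35.84, 92.74, 1.574, 81.17, 9.96)),
               c(36, 93, 1.6, 81, 10))
})

test_that("family prevalence per sorted fraction is the percent of subjects", {
  # 2 families, 3 IgA+ subjects with a single-IgA sample each
  asvs <- c("L1", "L2", "B1")
  samples <- paste0("S", 1:3, ".singleA")
  counts <- matrix(0L, 3, 3, dimnames = list(asvs, samples))
  counts["L1", 1] <- 5L      # Lachnospiraceae in subject 1
  counts["L2", 2] <- 3L      # Lachnospiraceae in subject 2
  counts["B1", c(1, 3)] <- 2L # Bacteroidaceae in subjects 1 and 3
  meta <- data.frame(sample_id = samples,
                     subject_id = paste0("S", 1:3),
                     pair_id = paste0("H", 1:3), iga_status = "IgA+",
                     fraction_type = "single_IgA", stringsAsFactors = FALSE)
  tax <- data.frame(asv_id = asvs, phylum = "x",
                    family = c("Lachnospiraceae", "Lachnospiraceae",
                               "Bacteroidaceae"), stringsAsFactors = FALSE)
  prev <- fraction_prevalence(presence_matrix(sorted_counts(counts, meta,
                                                            tax)))
  bf <- prev$by_family
  expect_equal(bf$prevalence_pct[bf$family == "Lachnospiraceae"],
               100 * 2 / 3)
  expect_equal(bf$prevalence_pct[bf$family == "Bacteroidaceae"],
               100 * 2 / 3)
  # per-subject overall prevalence vectors
  bs <- prev$by_subject
  expect_equal(bs$prop_families[bs$subject_id == "S1"], 1)
  expect_equal(bs$prop_families[bs$subject_id == "S2"], 0.5)
  # 8 of 16 subjects -> 50% by the same arithmetic
  expect_equal(100 * 8 / 16, 50)
})
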