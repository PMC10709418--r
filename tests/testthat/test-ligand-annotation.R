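test_that("AND-of-OR rule evaluation matches subset enumeration", {
  k <- c("K00001", "K00002", "K00003")
  rule <- list(c("K00001", "K00002"), "K00003")
  # all 2^3 profiles over the involved KOs
  for (i in 0:7) {
    profile <- k[bitwAnd(i, c(1, 2, 4)) > 0]
    expect_identical(evaluate_capability(profile, rule),
                     oracle_rule_satisfied(profile, rule),
                     label = paste("profile", paste(profile, collapse = ",")))
  }
  expect_false(evaluate_capability(character(0), rule))
  expect_true(evaluate_capability(k, rule))
  expect_true(evaluate_capability(c("K00002", "K00003"), rule))
  expect_false(evaluate_capability(c("K00001", "K00002"), rule))
  expect_error(evaluate_capability("notako", rule), "malformed")
})

test_that("rule evaluation is monotone and matches enumeration on random rules", {
  set.seed(17)
  universe <- sprintf("K%05d", 1:12)
  for (rep in 1:20) {
    rule <- replicate(sample(1:3, 1),
                      sample(universe, sample(1:3, 1)), simplify = FALSE)
    profile <- sample(universe, sample(0:12, 1))
    expect_identical(evaluate_capability(profile, rule),
                     oracle_rule_satisfied(profile, rule))
    # adding KOs never turns a satisfied rule unsatisfied
    if (evaluate_capability(profile, rule))
      expect_true(evaluate_capability(union(profile, sample(universe, 2)),
                                      rule))
  }
})

test_that("LPS calls refine from none to penta to hexa", {
  rules <- load_ligand_rules()
  core <- vapply(rules$lps_core$groups, `[`, character(1), 1)
  hexa <- vapply(rules$lps_hexa_extension$groups, `[`, character(1), 1)
  expect_equal(call_ligands(character(0), rules)$lps, "none")
  expect_equal(call_ligands(hexa, rules)$lps, "none")  # no core, no call
  expect_equal(call_ligands(core, rules)$lps, "penta")
  expect_equal(call_ligands(c(core, hexa), rules)$lps, "hexa")
  # butyrate needs a complete route plus the terminal group
  route <- vapply(rules$butyrate$routes[[1]], `[`, character(1), 1)
  terminal <- rules$butyrate$groups[[1]][1]
  expect_false(call_ligands(route, rules)$butyrate)
  expect_false(call_ligands(terminal, rules)$butyrate)
  expect_true(call_ligands(c(route, terminal), rules)$butyrate)
})

test_that("rulesets must cover all four capabilities and valid KOs", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "rules.json")
  jsonlite::write_json(list(flagellin = list(groups = list(list("K02406")))),
                       bad, auto_unbox = FALSE)
  expect_error(load_ligand_rules(bad), "lps_core")
  shipped <- load_ligand_rules()
  expect_s3_class(shipped, "ligand_rules")
  expect_equal(shipped$lps_core$map, "map00540")
})

test_that("synthetic KO profiles are called consistently with their families", {
  co <- generate_cohort(small_cohort_config(seed = 23))
  calls <- call_ligands_all(co$bundle$ko_profiles)
  tax <- co$truth$asvs
  calls$family <- tax$family[match(calls$taxon_id, tax$asv_id)]
  capfam <- igcoat:::capability_families()
  # hexa-acylated LPS only ever in the designated families
  expect_true(all(calls$family[calls$lps == "hexa"] %in% capfam$lps_hexa))
  # every LPS-capable family carries at least the penta call
  expect_true(all(calls$lps[calls$family %in% capfam$lps] != "none"))
  expect_true(all(calls$lps[!calls$family %in% capfam$lps] == "none"))
  expect_true(all(calls$family[calls$flagellin] %in% capfam$flagellin))
  expect_true(all(calls$family[calls$butyrate] %in% capfam$butyrate))
})

test_that("producer coating summaries reproduce a hand-computed toy case", {
  calls <- data.frame(taxon_id = paste0("T", 1:4),
                      flagellin = c(TRUE, TRUE, FALSE, FALSE),
                      lps = "none", butyrate = FALSE,
                      stringsAsFactors = FALSE)
  loads <- data.frame(subject_id = "S1", taxon_id = paste0("T", 1:4),
                      coated_load = c(10, 0, 5, 5),
                      total_load = c(20, 10, 10, 10),
                      stringsAsFactors = FALSE)
  ps <- producer_coating_summary(calls, loads)
  fl <- ps[ps$capability == "flagellin", ]
  expect_equal(fl$pct_producers, 50)
  expect_equal(fl$producer_coating_freq, 10 / 30)
  expect_equal(fl$coated_ratio, 11 / 11)  # (10+0)+1 over (5+5)+1
  # no producers: ratio below 1 for any positive non-producer load
  none <- ps[ps$capability == "butyrate", ]
  expect_lt(none$coated_ratio, 1)
  expect_error(
    producer_coating_summary(
      data.frame(taxon_id = "X1", flagellin = TRUE, lps = "none",
                 butyrate = FALSE),
      loads),
    "share no taxa")
})
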