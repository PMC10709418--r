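test_that("FMO thresholds follow the nearest-rank quantile rule", {
  fmo <- data.frame(event_id = 1:100, dapi = 5000,
                    iga = 1:100, igm = rep(7, 100), is_bead = FALSE)
  thr <- derive_thresholds(fmo, quantile = 0.999)
  expect_equal(unname(thr[["iga"]]), 100)   # highest order statistic
  expect_equal(unname(thr[["igm"]]), 7)     # constant distribution
  thr0 <- derive_thresholds(fmo, quantile = 0)
  expect_equal(unname(thr0[["iga"]]), 1)    # minimum
  expect_equal(attr(thr, "quantile"), 0.999)

  empty <- data.frame(event_id = integer(0), dapi = numeric(0),
                      iga = numeric(0), is_bead = logical(0))
  expect_error(derive_thresholds(empty), "iga")
})

test_that("event classification matches hand enumeration on a toy table", {
  prof <- classify_events(toy_events(), toy_thresholds())
  expect_s3_class(prof, "ig_profile")
  # events: (A,M,G)=(1,1,1),(1,0,0),(0,0,1),(1,1,0),(0,1,0),(0,0,0)
  expect_equal(prof$counts[["iga+igm+igg"]], 1)
  expect_equal(prof$counts[["iga"]], 1)
  expect_equal(prof$counts[["igg"]], 1)
  expect_equal(prof$counts[["iga+igm"]], 1)
  expect_equal(prof$counts[["igm"]], 1)
  expect_equal(prof$counts[["none"]], 1)
  expect_equal(prof$n_gated, 6)
  expect_equal(sum(prof$counts), prof$n_gated)
})

test_that("all-negative events, ties, and raised gates behave as specified", {
  ev <- toy_events()
  low <- toy_thresholds()
  low[] <- 10000  # everything below every threshold
  prof <- classify_events(ev, low)
  expect_equal(prof$counts[["none"]], 6)

  # ties at the threshold are negative (strict inequality)
  tie <- toy_thresholds()
  tie[["iga"]] <- 500
  prof_tie <- classify_events(ev, tie)
  expect_equal(marginal_count(prof_tie, "iga"), 0)

  # raising one gate zeroes its marginal, leaves others unchanged
  base <- classify_events(ev, toy_thresholds())
  up <- toy_thresholds(); up[["igg"]] <- 1e6
  raised <- classify_events(ev, up)
  expect_equal(marginal_count(raised, "igg"), 0)
  expect_equal(marginal_count(raised, "iga"), marginal_count(base, "iga"))
  expect_equal(marginal_count(raised, "igm"), marginal_count(base, "igm"))
})

test_that("gate monotonicity and the partition property hold on random events", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 500
    ev <- data.frame(event_id = seq_len(n), dapi = 5000,
                     iga = rexp(n, 1 / 200), igm = rexp(n, 1 / 200),
                     igg = rexp(n, 1 / 200),
                     is_bead = runif(n) < 0.05)
    thr <- structure(c(iga = 150, igm = 150, igg = 150),
                     class = "gate_thresholds")
    prof <- classify_events(ev, thr)
    expect_equal(sum(prof$counts), prof$n_gated)
    expect_equal(prof$n_gated + prof$n_beads, n)
    thr_hi <- thr; thr_hi[["iga"]] <- 400
    expect_lte(marginal_count(classify_events(ev, thr_hi), "iga"),
               marginal_count(prof, "iga"))
  }
})

test_that("the IgG1-4 subtype panel uses the same machinery at k = 4", {
  set.seed(3)
  n <- 200
  ev <- data.frame(event_id = 1:n, dapi = 5000,
                   igg1 = rexp(n, 1 / 100), igg2 = rexp(n, 1 / 100),
                   igg3 = rexp(n, 1 / 100), igg4 = rexp(n, 1 / 100),
                   is_bead = FALSE)
  thr <- structure(c(igg1 = 100, igg2 = 100, igg3 = 100, igg4 = 100),
                   class = "gate_thresholds")
  prof <- classify_events(ev, thr)
  expect_length(prof$counts, 16)
  expect_equal(sum(prof$counts), n)
  expect_equal(marginal_count(prof, "igg2", "single"),
               prof$counts[["igg2"]])
})

test_that("bead calibration arithmetic and its edge cases are exact", {
  al <- absolute_load(1000, 1000, 1e5, 150, 1)
  expect_equal(al$load, 1.5e7)
  expect_equal(absolute_load(0, 500, 1e5, 150, 1)$load, 0)
  expect_equal(absolute_load(2000, 1000, 1e5, 150, 1)$load, 3e7)
  expect_error(absolute_load(100, 0, 1e5, 150, 1), "calibration")
})

test_that("combination loads distribute and conserve the total load", {
  prof <- structure(list(
    counts = c(none = 50L, iga = 25L, igm = 25L, "iga+igm" = 0L),
    combo = cbind(iga = c(FALSE, TRUE, FALSE, TRUE),
                  igm = c(FALSE, FALSE, TRUE, TRUE)),
    channels = c("iga", "igm"), n_gated = 100L, n_beads = 0L),
    class = "ig_profile")
  loads <- combo_loads(prof, 1e10)
  expect_equal(unname(loads[c("iga", "igm", "none")]),
               c(2.5e9, 2.5e9, 5e9))
  expect_equal(sum(loads), 1e10, tolerance = 1e-9)

  set.seed(5)
  for (i in 1:10) {
    cnt <- as.integer(rmultinom(1, 1000, runif(4)))
    prof$counts[] <- cnt
    prof$n_gated <- sum(cnt)
    expect_equal(sum(combo_loads(prof, 2e10)), 2e10, tolerance = 1e-6)
  }
  prof$counts[] <- 0L; prof$n_gated <- 0L
  expect_error(combo_loads(prof, 1e10), "no DAPI")
})

test_that("coating fractions on simulated events recover the generating probabilities", {
  p <- c(iga = 0.09, igm = 0.02, igg = 0.015)
  ev <- simulate_flow_events(2e10, p, n_events = 50000,
                             beads_added = 1e5, seed = 91)
  prof <- classify_events(ev, sep_thresholds())
  frac <- coating_fractions(prof)
  n <- prof$n_gated
  for (ch in names(p)) {
    sd3 <- 3 * sqrt(p[[ch]] * (1 - p[[ch]]) / n)
    expect_lt(abs(frac[[ch]] - p[[ch]]), sd3)
  }
})
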