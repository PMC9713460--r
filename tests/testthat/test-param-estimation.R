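# Frozen expectations below are from the pooled-count arithmetic applied to
# the packaged OX-1 table: positives P = sum(round(rate * n)), per-pool GDBI
# fractions scaled to the marker-negatives, c = (P+G)/N, ch = P/(P+G).

test_that("pooled cutting estimates reproduce the study arithmetic", {
  cuts <- estimate_cut_params(ox1_pool_counts())
  nos_m <- cuts[cuts$line == "AeaNosC109" & cuts$parent_sex == "M", ]
  # P = 126 + 185 = 311; G = 102*9/54 + 29*7/27 = 24.5185; N = 442
  expect_equal(nos_m$n_marker_positive, 311)
  expect_equal(nos_m$n_gdbi_est, 102 * 9 / 54 + 29 * 7 / 27, tolerance = 1e-12)
  expect_lt(abs(nos_m$c - 0.759), 1e-3)
  expect_lt(abs(nos_m$ch - 0.927), 1e-3)
  expect_lt(abs(nos_m$cr - 0.073), 1e-3)

  # zero observed GDBI: the cut rate collapses onto the marker rate
  zpg_m <- cuts[cuts$line == "AeaZpgC109" & cuts$parent_sex == "M", ]
  expect_equal(zpg_m$c, 266 / 460, tolerance = 1e-12)
  expect_equal(zpg_m$ch, 1)
  expect_equal(zpg_m$cr, 0)
})

test_that("single Mendelian-looking pool gives c = 0.5, ch = 1", {
  pools <- tibble::tibble(
    line = "x", parent_sex = "M", marker_rate = 0.5, n_assessed = 200,
    gdbi_tested = 20, gdbi_positive = 0
  )
  est <- estimate_cut_params(pools)
  expect_equal(est$c, 0.5)
  expect_equal(est$ch, 1)
})

test_that("raw marker-positive counts bypass the rounding reconstruction", {
  pools <- tibble::tibble(
    line = "x", parent_sex = "F", marker_positive = 126, n_assessed = 228,
    gdbi_tested = 54, gdbi_positive = 9
  )
  est <- estimate_cut_params(pools)
  expect_equal(est$n_marker_positive, 126)
  expect_equal(est$c, (126 + 102 * 9 / 54) / 228, tolerance = 1e-12)
})

test_that("estimation is invariant to splitting a pool at identical rates", {
  one <- tibble::tibble(
    line = "x", parent_sex = "M", marker_positive = 120, n_assessed = 200,
    gdbi_tested = 40, gdbi_positive = 10
  )
  two <- tibble::tibble(
    line = "x", parent_sex = "M", marker_positive = c(60, 60),
    n_assessed = c(100, 100), gdbi_tested = c(20, 20), gdbi_positive = c(5, 5)
  )
  e1 <- estimate_cut_params(one)
  e2 <- estimate_cut_params(two)
  expect_equal(e1$c, e2$c, tolerance = 1e-12)
  expect_equal(e1$ch, e2$ch, tolerance = 1e-12)
})

test_that("untested pools fall back to the pooled GDBI fraction", {
  pools <- tibble::tibble(
    line = "x", parent_sex = "M", marker_positive = c(60, 70),
    n_assessed = c(100, 100), gdbi_tested = c(40, 0), gdbi_positive = c(10, 0)
  )
  est <- estimate_cut_params(pools)
  # both pools get fraction 10/40 applied to their marker-negatives
  expect_equal(est$n_gdbi_est, 40 * 0.25 + 30 * 0.25, tolerance = 1e-12)
  expect_error(
    estimate_cut_params(tibble::tibble(
      line = "x", parent_sex = "M", marker_positive = 0, n_assessed = 0,
      gdbi_tested = 0, gdbi_positive = 0
    )),
    "no pools"
  )
})

test_that("deposition rate is the mean eCFP-class activity fraction", {
  assay <- tibble::tibble(
    marker_class = c("eCFP", "eCFP", "eCFP", "mCherry"),
    n_larvae = c(10, 10, 10, 12),
    n_active_drive_locus = c(2, 4, 3, 9)
  )
  est <- estimate_deposition(assay)
  expect_equal(est$dF, 0.3)
  expect_equal(est$dhF, 0)
  expect_equal(est$drF, 1)

  all19 <- tibble::tibble(
    marker_class = "eCFP", n_larvae = c(100, 100, 100),
    n_active_drive_locus = c(19, 19, 19)
  )
  expect_equal(estimate_deposition(all19)$dF, 0.19)
  zero <- tibble::tibble(marker_class = "eCFP", n_larvae = 30,
                         n_active_drive_locus = 0)
  expect_equal(estimate_deposition(zero)$dF, 0)
  expect_error(
    estimate_deposition(tibble::tibble(marker_class = "mCherry",
                                       n_larvae = 10,
                                       n_active_drive_locus = 1)),
    "eCFP"
  )
})

test_that("lifecycle derivation follows the fecundity and viability rules", {
  fit <- tibble::tibble(
    line = c("wt", "gd_cost", "gd_free", "gd_ns"),
    fecundity_mean = c(76, 75, 80, 75),
    larval_viability = c(0.80, 0.70, 0.80, 0.70),
    larva_to_pupa_days = c(6.1, 6.3, 5.6, 6.0),
    viability_significant = c(NA, TRUE, FALSE, FALSE)
  )
  gd <- derive_lifecycle(fit, "gd_cost", "wt")
  expect_equal(gd$betaK, 75 * 4 / 11, tolerance = 1e-12)
  expect_equal(gd$tLarva, 6L)
  expect_equal(gd$xiF, 0.90)
  expect_equal(gd$fertility_mult, 0.9)
  # no viability deficit -> no modifier
  expect_equal(derive_lifecycle(fit, "gd_free", "wt")$xiF, 1)
  # deficit present but not significant -> no modifier (the "NULL" case)
  expect_equal(derive_lifecycle(fit, "gd_ns", "wt")$xiF, 1)
  expect_error(derive_lifecycle(fit, "gd_cost", "nope"), "reference")
})

test_that("estimates recover known rates from synthetic crosses", {
  set.seed(77)
  truth <- drive_params(cF = 0.76, cM = 0.76, chF = 0.93, chM = 0.93,
                        crF = 0.07, crM = 0.07, dF = 0.19)
  ok <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    synth <- synth_cross_dataset(truth, n_families = 50,
                                 transmission = "estimation",
                                 size_mean = 60, size_min = 60, size_max = 60,
                                 gdbi_test_fraction = 1)
    est <- estimate_cut_params(synth$pools)
    assay <- synth_transhet(truth, n_per_rep = 300, reps = 3)
    dep <- estimate_deposition(assay)
    if (all(abs(est$c - 0.76) < 0.05) && all(abs(est$ch - 0.93) < 0.05) &&
        abs(dep$dF - 0.19) < 0.05) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_rep, 0.9)
})
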