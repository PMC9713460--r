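test_that("calibration holds wild-type adults at equilibrium for a year", {
  calib <- calibrate_equilibrium(lifecycle_params())
  sim <- simulate_release(mendelian_cube(), calib, drive_params(),
                          release = NULL, days = 365, mode = "deterministic")
  totals <- rowSums(sim$reps[[1]]$f) + rowSums(sim$reps[[1]]$m)
  expect_true(all(totals >= 0.98 * 10000 & totals <= 1.02 * 10000))
})

test_that("calibration contract holds across random valid parameter sets", {
  set.seed(11)
  for (i in 1:8) {
    lc <- lifecycle_params(
      tEgg = sample(3:6, 1), tLarva = sample(4:9, 1), tPupa = sample(1:3, 1),
      betaK = runif(1, 15, 40), muAD = runif(1, 0.05, 0.2),
      popGrowth = runif(1, 1.05, 2), N_eq = 5000
    )
    calib <- calibrate_equilibrium(lc)
    sim <- simulate_release(mendelian_cube(), calib, drive_params(),
                            release = NULL, days = 365,
                            mode = "deterministic")
    totals <- rowSums(sim$reps[[1]]$f) + rowSums(sim$reps[[1]]$m)
    expect_true(all(abs(totals - 5000) <= 0.02 * 5000))
  }
})

test_that("unsustainable demography fails calibration with a diagnostic", {
  expect_error(calibrate_equilibrium(lifecycle_params(muAD = 1)),
               "calibration error")
  expect_error(calibrate_equilibrium(lifecycle_params(popGrowth = 0.9)),
               "not self-sustaining")
  expect_error(
    calibrate_equilibrium(lifecycle_params(betaK = 0.3, muAD = 0.5)),
    "calibration error"
  )
})

test_that("recalibration absorbs a fecundity change into the same equilibrium", {
  c1 <- calibrate_equilibrium(lifecycle_params(betaK = 20))
  c2 <- calibrate_equilibrium(lifecycle_params(betaK = 40))
  for (calib in list(c1, c2)) {
    sim <- simulate_release(mendelian_cube(), calib, drive_params(),
                            release = NULL, days = 120,
                            mode = "deterministic")
    totals <- rowSums(sim$reps[[1]]$f) + rowSums(sim$reps[[1]]$m)
    expect_equal(totals[120], 10000, tolerance = 1e-6)
  }
})

test_that("neutral Mendelian inheritance keeps allele frequencies constant", {
  calib <- calibrate_equilibrium(lifecycle_params(N_eq = 4000))
  sim <- simulate_release(mendelian_cube(), calib, drive_params(),
                          release = release_schedule(day = 5, count = 800),
                          days = 500, mode = "deterministic")
  r <- sim$reps[[1]]
  nH <- c(0, 1, 0, 2, 1, 0)
  freq <- function(d) {
    ad <- r$f[d, ] + r$m[d, ]
    sum(ad * nH) / (2 * sum(ad))
  }
  late <- vapply(seq(350, 500, by = 10), freq, numeric(1))
  expect_gt(late[1], 0.01)  # the released allele persists
  expect_lt(max(abs(diff(late))), 1e-6)
})

test_that("a perfect cost-free drive fixes and eliminates wild-type", {
  params <- drive_params(cF = 1, cM = 1, chF = 1, chM = 1, crF = 0, crM = 0)
  calib <- calibrate_equilibrium(lifecycle_params(N_eq = 4000))
  sim <- simulate_release(build_cube(params), calib, params,
                          release = release_schedule(day = 25, count = 800),
                          days = 700, mode = "deterministic")
  m <- summary_metrics(sim)
  expect_false(is.na(m$day_ww_eliminated))
  expect_true(is.na(m$day_h_eliminated))
  expect_equal(m$final_freq_h, 1, tolerance = 1e-6)
  cov <- effector_coverage(sim)
  expect_gt(max(cov$coverage), 0.999)
})

test_that("equal seeds reproduce trajectories; different seeds diverge", {
  params <- drive_params(cF = 0.7, cM = 0.7, chF = 0.9, chM = 0.9,
                         crF = 0.1, crM = 0.1, dF = 0.1)
  cube <- build_cube(params)
  calib <- calibrate_equilibrium(lifecycle_params(N_eq = 2000))
  rel <- release_schedule(day = 10, count = 400)
  s1 <- simulate_release(cube, calib, params, rel, days = 60, reps = 2, seed = 42)
  s2 <- simulate_release(cube, calib, params, rel, days = 60, reps = 2, seed = 42)
  s3 <- simulate_release(cube, calib, params, rel, days = 60, reps = 2, seed = 43)
  expect_identical(tidy(s1), tidy(s2))
  expect_false(identical(tidy(s1), tidy(s3)))
  # replicates use distinct streams
  expect_false(identical(s1$reps[[1]]$f, s1$reps[[2]]$f))
})

test_that("stochastic state counts stay non-negative integers", {
  params <- drive_params(cF = 0.8, cM = 0.8, chF = 0.93, chM = 0.93,
                         crF = 0.07, crM = 0.07, dF = 0.19,
                         fertility_mult = 0.9, xiF = 0.9, xiM = 0.9)
  calib <- calibrate_equilibrium(lifecycle_params(N_eq = 2000))
  sim <- simulate_release(build_cube(params), calib, params,
                          release = release_schedule(day = 10, count = 400),
                          days = 150, reps = 2, seed = 7)
  traj <- tidy(sim)
  expect_true(all(traj$count >= 0))
  expect_true(all(traj$count == round(traj$count)))
  expect_true(all(sim$reps[[1]]$h >= 0))
})

test_that("stochastic mean tracks the deterministic wild-type trajectory", {
  calib <- calibrate_equilibrium(lifecycle_params())
  det <- simulate_release(mendelian_cube(), calib, drive_params(),
                          release = NULL, days = 150, mode = "deterministic")
  sto <- simulate_release(mendelian_cube(), calib, drive_params(),
                          release = NULL, days = 150, reps = 30, seed = 99)
  det_tot <- rowSums(det$reps[[1]]$f) + rowSums(det$reps[[1]]$m)
  sto_tot <- Reduce(`+`, lapply(sto$reps, function(r) {
    rowSums(r$f) + rowSums(r$m)
  })) / sto$n_reps
  expect_true(all(abs(sto_tot - det_tot) / det_tot < 0.05))
})

test_that("coverage and outcome metrics read trajectories correctly", {
  # hand-built single-rep object: 50 WW, 30 WH, 20 HR females
  fake <- structure(
    list(
      reps = list(list(
        f = matrix(c(50, 30, 0, 0, 20, 0), 1, 6),
        m = matrix(c(10, 0, 0, 0, 0, 0), 1, 6),
        aq = matrix(0, 1, 6),
        h = 70
      )),
      days = 1, n_reps = 1, mode = "deterministic", seed = NULL,
      release_day = 0L, release = release_schedule(count = 0)[0, ],
      lc = lifecycle_params(), params = drive_params(),
      genotypes = drive_genotypes()
    ),
    class = "gd_sim"
  )
  expect_equal(effector_coverage(fake)$coverage, 0.5)
  m <- summary_metrics(fake)
  expect_true(is.na(m$day_ww_eliminated))
  expect_equal(m$peak_coverage, 0.5)
})

test_that("scenario substitution replaces only the named fields", {
  base <- list(
    params = drive_params(cF = 0.8, chF = 0.93, crF = 0.07, dF = 0.19,
                          xiF = 0.9, xiM = 0.9, fertility_mult = 0.9),
    lifecycle = lifecycle_params()
  )
  same <- scenario_substitute(base, list())
  expect_equal(unclass(same$params), unclass(base$params))
  expect_equal(unclass(same$lifecycle), unclass(base$lifecycle))

  hybrid <- scenario_substitute(
    base, list(crF = 0, crM = 0, chF = 1, chM = 1, dF = 0.14, xiF = 1, xiM = 1)
  )
  hand <- drive_params(cF = 0.8, chF = 1, crF = 0, dF = 0.14,
                       xiF = 1, xiM = 1, fertility_mult = 0.9)
  expect_equal(unclass(hybrid$params), unclass(hand))
  expect_equal(unclass(hybrid$params)$dF, 0.14)
  ov <- attr(hybrid, "overrides")
  expect_setequal(ov$field, c("crF", "crM", "chF", "chM", "dF", "xiF", "xiM"))
  expect_error(scenario_substitute(base, list(nope = 1)), "unknown parameter")
})

test_that("autoplot and coverage plots return ggplot objects", {
  calib <- calibrate_equilibrium(lifecycle_params(N_eq = 1000))
  sim <- simulate_release(mendelian_cube(), calib, drive_params(),
                          release = release_schedule(day = 5, count = 100),
                          days = 30, reps = 1, seed = 2)
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_s3_class(plot_coverage(sim), "ggplot")
})
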