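test_that("gamete distributions are Mendelian without cutting and biased with it", {
  p0 <- drive_params()
  expect_equal(gamete_distribution("WH", "F", p0), c(W = 0.5, H = 0.5, R = 0))
  expect_equal(gamete_distribution("HH", "M", p0), c(W = 0, H = 1, R = 0))
  expect_equal(gamete_distribution("WR", "F", drive_params(cF = 0.9, chF = 0.5)),
               c(W = 0.5, H = 0, R = 0.5))  # no H on board, no cutting
  expect_equal(gamete_distribution("RR", "M", p0), c(W = 0, H = 0, R = 1))

  # germline cutting in a hemizygote: P(H) = 1/2 + 1/2 c ch etc.
  p <- drive_params(cF = 0.759, chF = 0.927, crF = 0.073)
  g <- gamete_distribution("WH", "F", p)
  expect_equal(sum(g), 1)
  expect_equal(g, oracle_gametes("WH", "F", p), tolerance = 1e-12)
  expect_equal(unname(g["H"]), 0.5 + 0.5 * 0.759 * 0.927)
  expect_equal(unname(g["W"]), 0.5 * (1 - 0.759))
})

test_that("gamete distribution rejects bad inputs", {
  expect_error(gamete_distribution("WE", "F", drive_params()), "genotype")
  expect_error(drive_params(cF = 1.2), "probability")
  expect_error(drive_params(chF = 0.5, crF = 0.2), "resolution")
})

test_that("zygote distribution composes gametes and maternal deposition", {
  # WW mother carries no H: no deposition path exists
  expect_equal(
    zygote_distribution("WW", "WW", drive_params(dF = 0.7)),
    c(WW = 1, WH = 0, WR = 0, HH = 0, HR = 0, RR = 0)
  )
  # all maternal gametes H; paternal W deposited to R half the time
  p <- drive_params(cF = 1, chF = 1, dF = 0.5, dhF = 0, drF = 1)
  z <- zygote_distribution("WH", "WW", p)
  expect_equal(unname(z[c("WH", "HR")]), c(0.5, 0.5))
  # general case matches the independent event-tree enumerator
  p2 <- drive_params(cF = 0.759, chF = 0.927, dF = 0.19)
  expect_equal(zygote_distribution("WH", "WW", p2),
               oracle_zygote("WH", "WW", p2), tolerance = 1e-12)
})

test_that("cube equals the Mendelian oracle when cutting and deposition are off", {
  expect_equal(unclass(build_cube(drive_params())), unclass(mendelian_cube()),
               ignore_attr = TRUE)
  m <- mendelian_cube()
  expect_equal(m["WH", "WH", ],
               c(WW = 0.25, WH = 0.5, WR = 0, HH = 0.25, HR = 0, RR = 0))
  expect_equal(m["WR", "HR", ],
               c(WW = 0, WH = 0.25, WR = 0.25, HH = 0, HR = 0.25, RR = 0.25))
})

test_that("every cube row is a probability distribution and matches enumeration", {
  set.seed(401)
  for (i in 1:25) {
    p <- random_drive_params()
    cube <- build_cube(p)
    sums <- apply(cube, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(cube >= 0))
    expect_equal(unclass(cube), oracle_cube(p), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("marker-inheritance marginal is 1/2 (1 + c ch) and monotone", {
  marginal <- function(c_s, ch_s) {
    cube <- build_cube(drive_params(cM = c_s, chM = ch_s, crM = 1 - ch_s))
    row <- cube["WW", "WH", ]
    sum(row[c("WH", "HH", "HR")])
  }
  set.seed(402)
  for (i in 1:10) {
    c_s <- runif(1); ch_s <- runif(1)
    expect_equal(marginal(c_s, ch_s), 0.5 * (1 + c_s * ch_s), tolerance = 1e-12)
  }
  grid <- seq(0, 1, by = 0.25)
  expect_true(all(diff(vapply(grid, marginal, numeric(1), ch_s = 0.8)) >= 0))
  expect_true(all(diff(vapply(grid, marginal, numeric(1), c_s = 0.8)) >= 0))
})

test_that("perfect homing with no deposition never creates resistance alleles", {
  cube <- build_cube(drive_params(cF = 0.9, cM = 0.7, chF = 1, chM = 1,
                                  crF = 0, crM = 0, dF = 0))
  r_mass <- apply(cube, c(1, 2), function(row) sum(row[c("WR", "HR", "RR")]))
  no_r_parents <- setdiff(drive_genotypes(), c("WR", "HR", "RR"))
  expect_true(all(r_mass[no_r_parents, no_r_parents] == 0))
})

test_that("cube CSV round trip preserves probabilities at full precision", {
  cube <- build_cube(drive_params(cF = 1 / 3, chF = 0.927, dF = 0.19))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cube_csv(cube, path)
  back <- read_cube_csv(path)
  expect_equal(unclass(back), unclass(cube), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(read_cube_csv(withr::local_tempfile(lines = "a,b\n1,2")),
               "missing")
})
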