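# Stage-structured demography: lifecycle parameters and equilibrium
# calibration for the daily-time-step population model.

#' Lifecycle and demographic parameters
#'
#' Stage durations are whole days; the aquatic pipeline is
#' egg (`tEgg` days) -> larva (`tLarva` days) -> pupa (`tPupa` days) ->
#' adult. `betaK` is daily egg output per mated female, derived from a
#' fecundity of ~75 eggs per gonotrophic cycle x 4 blood meals over an
#' 11-day urban adult lifespan. `popGrowth` is the per-generation growth
#' rate of the population at low density and, together with `muAD`, fixes
#' the density-independent daily aquatic survival (see
#' [calibrate_equilibrium()]).
#'
#' @param tEgg,tLarva,tPupa Stage durations in days (defaults 5, 6, 2).
#' @param betaK Eggs per mated female per day.
#' @param muAD Adult daily mortality probability (default 0.123).
#' @param popGrowth Per-generation low-density growth rate (default 1.175).
#' @param N_eq Target equilibrium adult count (default 10,000).
#' @param sex_ratio Fraction of emerging adults that are female (default 0.5).
#' @return A `lifecycle_params` object (validated named list).
#' @export
#' @examples
#' lifecycle_params()
lifecycle_params <- function(tEgg = 5, tLarva = 6, tPupa = 2,
                             betaK = 75 * 4 / 11, muAD = 0.123,
                             popGrowth = 1.175, N_eq = 10000,
                             sex_ratio = 0.5) {
  lc <- list(
    tEgg = as.integer(tEgg), tLarva = as.integer(tLarva),
    tPupa = as.integer(tPupa), betaK = betaK, muAD = muAD,
    popGrowth = popGrowth, N_eq = N_eq, sex_ratio = sex_ratio
  )
  class(lc) <- "lifecycle_params"
  validate_lifecycle_params(lc)
  lc
}

validate_lifecycle_params <- function(lc) {
  if (lc$tEgg < 1 || lc$tLarva < 1 || lc$tPupa < 1) {
    abort("lifecycle_params: stage durations must be at least 1 day")
  }
  if (!is.numeric(lc$betaK) || lc$betaK <= 0) {
    abort("lifecycle_params: betaK must be positive")
  }
  if (lc$muAD <= 0 || lc$muAD > 1) {
    abort("lifecycle_params: muAD must be in (0, 1]")
  }
  if (lc$popGrowth <= 0) abort("lifecycle_params: popGrowth must be positive")
  if (lc$N_eq <= 0) abort("lifecycle_params: N_eq must be positive")
  if (lc$sex_ratio <= 0 || lc$sex_ratio >= 1) {
    abort("lifecycle_params: sex_ratio must be in (0, 1)")
  }
  invisible(lc)
}

#' @export
print.lifecycle_params <- function(x, ...) {
  cat("<lifecycle_params>\n")
  cat(sprintf("  stages: egg %dd, larva %dd, pupa %dd\n", x$tEgg, x$tLarva, x$tPupa))
  cat(sprintf("  betaK %.3f eggs/female/day, muAD %.3f/day\n", x$betaK, x$muAD))
  cat(sprintf("  popGrowth %.3f/generation, N_eq %d adults\n",
              x$popGrowth, as.integer(x$N_eq)))
  invisible(x)
}

#' Calibrate the density-dependent equilibrium
#'
#' Solves the demographic parameters so that a wild-type-only population sits
#' exactly at `N_eq` adults. The daily update applies a density-independent
#' survival `s` to every aquatic cohort and an additional logistic-style
#' crowding factor `D = gamma / (gamma + L_total)` to larvae only, where
#' `L_total` is the current larval census.
#'
#' The calibration is closed-form. Writing `sA = 1 - muAD` and
#' `tAq = tEgg + tLarva + tPupa`:
#'
#' * `s` is fixed by requiring the low-density per-generation growth
#'   `R0 = betaK * sA / (2 muAD) * s^tAq` to equal `popGrowth`;
#' * at equilibrium each generation must exactly replace itself, giving the
#'   equilibrium crowding factor `D* = popGrowth^(-1/tLarva)`;
#' * the equilibrium larval census `L*` follows from the daily egg input
#'   `E0 = betaK * sA * N_eq / 2`, and `gamma = L* D* / (1 - D*)`.
#'
#' A deterministic run seeded from the returned state therefore holds adults
#' at `N_eq` indefinitely (up to floating-point error). Calibration fails
#' when the population is not self-sustaining (`popGrowth <= 1`) or when no
#' daily survival in (0, 1) can deliver the required growth (e.g. `muAD`
#' close to 1).
#'
#' @param lc A [lifecycle_params()] object.
#' @return A `gd_equilibrium` object: list with `lc`, `s_aquatic`, `D_star`,
#'   `gamma`, `E0`, `L_star` and the seeded wild-type `state`.
#' @export
#' @examples
#' calib <- calibrate_equilibrium(lifecycle_params())
#' calib$gamma
calibrate_equilibrium <- function(lc) {
  validate_lifecycle_params(lc)
  sA <- 1 - lc$muAD
  tAq <- lc$tEgg + lc$tLarva + lc$tPupa
  if (lc$popGrowth <= 1) {
    abort(paste0(
      "calibration error: popGrowth = ", format(lc$popGrowth),
      " <= 1, population is not self-sustaining"
    ))
  }
  if (sA <= 0) {
    abort("calibration error: muAD = 1 leaves no surviving adults to reproduce")
  }
  x <- 2 * lc$muAD * lc$popGrowth / (lc$betaK * sA)
  if (x >= 1) {
    abort(paste0(
      "calibration error: required aquatic survival ", format(x^(1 / tAq)),
      " >= 1; population not sustainable with betaK = ", format(lc$betaK),
      ", muAD = ", format(lc$muAD)
    ))
  }
  s <- x^(1 / tAq)
  D_star <- lc$popGrowth^(-1 / lc$tLarva)
  E0 <- lc$betaK * sA * lc$N_eq / 2

  gt <- drive_genotypes()
  egg <- matrix(0, lc$tEgg, 6, dimnames = list(NULL, gt))
  larva <- matrix(0, lc$tLarva, 6, dimnames = list(NULL, gt))
  pupa_f <- matrix(0, lc$tPupa, 6, dimnames = list(NULL, gt))
  pupa_m <- matrix(0, lc$tPupa, 6, dimnames = list(NULL, gt))
  egg[, "WW"] <- E0 * s^(seq_len(lc$tEgg) - 1)
  larva[, "WW"] <- E0 * s^lc$tEgg * (s * D_star)^(seq_len(lc$tLarva) - 1)
  p0 <- E0 * s^lc$tEgg * (s * D_star)^lc$tLarva
  pupa_f[, "WW"] <- lc$sex_ratio * p0 * s^(seq_len(lc$tPupa) - 1)
  pupa_m[, "WW"] <- (1 - lc$sex_ratio) * p0 * s^(seq_len(lc$tPupa) - 1)
  L_star <- sum(larva)
  gamma <- L_star * D_star / (1 - D_star)

  males <- setNames(numeric(6), gt)
  males["WW"] <- lc$N_eq / 2
  mated <- matrix(0, 6, 6, dimnames = list(female = gt, mate = gt))
  mated["WW", "WW"] <- lc$N_eq / 2
  unmated <- setNames(numeric(6), gt)

  structure(
    list(
      lc = lc, s_aquatic = s, D_star = D_star, gamma = gamma,
      E0 = E0, L_star = L_star,
      state = list(
        egg = egg, larva = larva, pupa_f = pupa_f, pupa_m = pupa_m,
        males = males, mated = mated, unmated = unmated
      )
    ),
    class = "gd_equilibrium"
  )
}

#' @export
print.gd_equilibrium <- function(x, ...) {
  cat("<gd_equilibrium>\n")
  cat(sprintf("  N_eq %d adults; daily aquatic survival %.4f\n",
              as.integer(x$lc$N_eq), x$s_aquatic))
  cat(sprintf("  equilibrium crowding D* = %.4f, gamma = %.1f, larvae %.0f\n",
              x$D_star, x$gamma, x$L_star))
  invisible(x)
}

#' Single-release schedule
#'
#' @param day Simulation day(s) of release (day 1 is the first simulated
#'   day).
#' @param sex `"M"` or `"F"` per event.
#' @param genotype Released genotype per event.
#' @param count Individuals released per event.
#' @return A tibble with one row per release event.
#' @export
#' @examples
#' release_schedule()  # 2,000 drive-homozygous males at day 25
release_schedule <- function(day = 25, sex = "M", genotype = "HH",
                             count = 2000) {
  rel <- tibble(day = as.integer(day), sex = sex, genotype = genotype,
                count = count)
  if (any(rel$count < 0)) abort("release_schedule: counts must be >= 0")
  if (any(rel$day < 1)) abort("release_schedule: days must be >= 1")
  if (any(!rel$sex %in% c("M", "F"))) abort("release_schedule: sex must be 'M' or 'F'")
  if (any(!rel$genotype %in% drive_genotypes())) {
    abort("release_schedule: unknown genotype")
  }
  rel
}
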