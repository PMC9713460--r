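# Daily-time-step population simulation driven by an inheritance cube.

# H-allele dosage per genotype, in canonical order.
h_dosage <- function() c(WW = 0, WH = 1, WR = 0, HH = 2, HR = 1, RR = 0)
allele_dosage <- function(allele) {
  vapply(
    strsplit(drive_genotypes(), ""),
    function(a) sum(a == allele), numeric(1)
  )
}

#' Simulate single-release population-replacement scenarios
#'
#' Runs the stage-structured daily model from the calibrated wild-type
#' equilibrium. Each simulated day applies, in order:
#'
#' 1. adult mortality (survival probability `1 - muAD`);
#' 2. mating of previously unmated females (mate genotype drawn in
#'    proportion to current adult males; females failing to find a mate
#'    retry the next day);
#' 3. oviposition: each surviving mated female lays `betaK` eggs per day
#'    (Poisson in stochastic mode), scaled by the fertility multiplier of
#'    her genotype; offspring genotypes follow the inheritance-cube row of
#'    the (mother, mate) pair;
#' 4. aquatic aging with daily survival `s`; larvae additionally experience
#'    the crowding factor `gamma / (gamma + L_total)`; graduating larvae are
#'    split 50:50 into sexes and thinned by the pupation-success multiplier
#'    `xiF`/`xiM` of drive-carrying genotypes; pupae completing `tPupa` days
#'    emerge, males join the mating pool first and newly emerged females
#'    mate immediately;
#' 5. scheduled releases are added to the adult pool.
#'
#' In stochastic mode every transition is a binomial/Poisson/multinomial
#' draw and all state counts are non-negative integers; deterministic mode
#' propagates expectations (real-valued state). Per-replicate random streams
#' are derived from `seed` so runs are reproducible and replicates
#' independent.
#'
#' @param cube An `inheritance_cube` from [build_cube()].
#' @param calib A `gd_equilibrium` from [calibrate_equilibrium()].
#' @param params The [drive_params()] supplying fitness modifiers
#'   (`fertility_mult`, `xiF`, `xiM`). Defaults to the cube's own parameters.
#' @param release A [release_schedule()] tibble (or `NULL` for no release).
#' @param days Number of days to simulate.
#' @param reps Number of replicates (ignored in deterministic mode).
#' @param seed Integer seed for the stochastic mode.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param fertility_scope Apply the fertility multiplier to the mother's
#'   genotype only (`"female"`, default) or to both parents (`"both"`).
#' @return A `gd_sim` object; use [tidy()] for the long trajectory table,
#'   [glance()] / [summary_metrics()] for outcome summaries and
#'   [effector_coverage()] for the drive-carrier coverage series.
#' @export
#' @examples
#' calib <- calibrate_equilibrium(lifecycle_params(N_eq = 1000))
#' cube <- build_cube(drive_params(cF = 0.8, cM = 0.8, chF = 0.95, chM = 0.95))
#' sim <- simulate_release(cube, calib, release = release_schedule(count = 200),
#'                         days = 120, reps = 2, seed = 1)
#' glance(sim)
simulate_release <- function(cube, calib, params = attr(cube, "params"),
                             release = release_schedule(), days,
                             reps = 1, seed = NULL,
                             mode = c("stochastic", "deterministic"),
                             fertility_scope = c("female", "both")) {
  mode <- match.arg(mode)
  fertility_scope <- match.arg(fertility_scope)
  if (!inherits(calib, "gd_equilibrium")) {
    abort("simulate_release: `calib` must come from calibrate_equilibrium()")
  }
  validate_cube(unclass(cube))
  if (is.null(params)) params <- drive_params()
  validate_drive_params(params)
  if (days < 1) abort("simulate_release: days must be >= 1")
  if (mode == "deterministic") reps <- 1L
  if (mode == "stochastic" && is.null(seed)) {
    abort("simulate_release: stochastic mode requires a seed")
  }

  gt <- drive_genotypes()
  cube_arr <- unclass(cube)
  cube_row <- function(m_idx, f_idx) cube_arr[m_idx, f_idx, ]

  hvec <- h_dosage()
  is_h <- hvec > 0
  fert <- ifelse(is_h, params$fertility_mult, 1)
  xiF <- ifelse(is_h, params$xiF, 1)
  xiM <- ifelse(is_h, params$xiM, 1)
  nW <- allele_dosage("W"); nH <- allele_dosage("H"); nR <- allele_dosage("R")

  lc <- calib$lc
  s <- calib$s_aquatic
  gamma <- calib$gamma
  sA <- 1 - lc$muAD
  stoch <- mode == "stochastic"

  rel <- if (is.null(release)) release_schedule(count = 0)[0, ] else release
  release_day <- if (nrow(rel) > 0) min(rel$day) else 0L

  traj_list <- vector("list", reps)
  for (rep_i in seq_len(reps)) {
    if (stoch) set.seed(rep_seed(seed, rep_i))
    st <- calib$state
    if (stoch) {
      st <- lapply(st, function(x) {
        x[] <- round(x)
        x
      })
    }
    egg <- st$egg; larva <- st$larva
    pupa_f <- st$pupa_f; pupa_m <- st$pupa_m
    males <- st$males; mated <- st$mated; unmated <- st$unmated

    rec_f <- matrix(0, days, 6); rec_m <- matrix(0, days, 6)
    rec_aq <- matrix(0, days, 6); rec_h <- numeric(days)

    for (day in seq_len(days)) {
      # 1. adult survival
      if (stoch) {
        males <- rbinom(6L, males, sA)
        mated[] <- rbinom(36L, as.vector(mated), sA)
        unmated <- rbinom(6L, unmated, sA)
      } else {
        males <- males * sA; mated <- mated * sA; unmated <- unmated * sA
      }

      # 2. carried-over unmated females try again
      if (sum(unmated) > 0 && sum(males) > 0) {
        mated <- mated + mate_females(unmated, males, stoch)
        unmated[] <- 0
      }

      # 3. oviposition
      eggs_new <- numeric(6)
      nz <- which(mated > 0, arr.ind = TRUE)
      if (nrow(nz) > 0) {
        for (k in seq_len(nrow(nz))) {
          fg <- nz[k, 1]; mg <- nz[k, 2]
          lambda <- lc$betaK * fert[fg] * mated[fg, mg]
          if (fertility_scope == "both") lambda <- lambda * fert[mg]
          n_eggs <- if (stoch) rpois(1L, lambda) else lambda
          if (n_eggs > 0) {
            p <- cube_row(fg, mg)
            if (stoch) {
              eggs_new <- eggs_new + rmultinom(1L, n_eggs, p)[, 1]
            } else {
              eggs_new <- eggs_new + n_eggs * p
            }
          }
        }
      }

      # 4. aquatic aging
      L_tot <- sum(larva)
      D <- gamma / (gamma + L_tot)

      emerge_f <- surv_vec(pupa_f[lc$tPupa, ], s, stoch)
      emerge_m <- surv_vec(pupa_m[lc$tPupa, ], s, stoch)
      if (lc$tPupa > 1) {
        for (a in rev(seq_len(lc$tPupa - 1))) {
          pupa_f[a + 1, ] <- surv_vec(pupa_f[a, ], s, stoch)
          pupa_m[a + 1, ] <- surv_vec(pupa_m[a, ], s, stoch)
        }
      }

      grad <- surv_vec(larva[lc$tLarva, ], s * D, stoch)
      if (stoch) {
        grad_f <- rbinom(6L, grad, lc$sex_ratio)
      } else {
        grad_f <- grad * lc$sex_ratio
      }
      grad_m <- grad - grad_f
      pupa_f[1, ] <- surv_vec(grad_f, xiF, stoch)
      pupa_m[1, ] <- surv_vec(grad_m, xiM, stoch)

      if (lc$tLarva > 1) {
        for (a in rev(seq_len(lc$tLarva - 1))) {
          larva[a + 1, ] <- surv_vec(larva[a, ], s * D, stoch)
        }
      }
      larva[1, ] <- surv_vec(egg[lc$tEgg, ], s, stoch)

      if (lc$tEgg > 1) {
        for (a in rev(seq_len(lc$tEgg - 1))) {
          egg[a + 1, ] <- surv_vec(egg[a, ], s, stoch)
        }
      }
      egg[1, ] <- eggs_new

      # males join the pool before the new females choose mates
      males <- males + emerge_m

      # 5. releases (added before the day's mating so released males count)
      if (nrow(rel) > 0) {
        todays <- rel[rel$day == day, , drop = FALSE]
        if (nrow(todays) > 0) {
          for (k in seq_len(nrow(todays))) {
            gi <- match(todays$genotype[k], gt)
            if (todays$sex[k] == "M") {
              males[gi] <- males[gi] + todays$count[k]
            } else {
              unmated[gi] <- unmated[gi] + todays$count[k]
            }
          }
        }
      }

      if (sum(emerge_f) > 0) {
        if (sum(males) > 0) {
          mated <- mated + mate_females(emerge_f, males, stoch)
        } else {
          unmated <- unmated + emerge_f
        }
      }

      if (stoch && (any(males < 0) || any(mated < 0) || any(egg < 0) ||
                    any(larva < 0) || any(pupa_f < 0) || any(pupa_m < 0))) {
        abort("simulate_release: internal invariant violation (negative count)")
      }

      fem <- colSums(mated) + unmated
      aq <- colSums(egg) + colSums(larva) + colSums(pupa_f) + colSums(pupa_m)
      rec_f[day, ] <- fem
      rec_m[day, ] <- males
      rec_aq[day, ] <- aq
      # H alleles anywhere in the population, including sperm stored by
      # mated females (those can still found H offspring)
      rec_h[day] <- sum((fem + males + aq) * nH) + sum(t(mated) * nH)
    }

    traj_list[[rep_i]] <- list(f = rec_f, m = rec_m, aq = rec_aq, h = rec_h)
  }

  structure(
    list(
      reps = traj_list, days = days, n_reps = reps, mode = mode,
      seed = seed, release_day = release_day, release = rel,
      lc = lc, params = params, genotypes = gt
    ),
    class = "gd_sim"
  )
}

rep_seed <- function(seed, rep_i) {
  (as.integer(seed) %% 100000L) * 20011L + rep_i * 7919L
}

surv_vec <- function(x, p, stoch) {
  if (stoch) rbinom(length(x), x, p) else x * p
}

# Assign mates to `females` (counts per genotype) in proportion to the male
# genotype abundances; returns a 6 x 6 (female x mate) matrix.
mate_females <- function(females, males, stoch) {
  out <- matrix(0, 6, 6)
  pm <- males / sum(males)
  for (fg in which(females > 0)) {
    if (stoch) {
      out[fg, ] <- rmultinom(1L, females[fg], pm)[, 1]
    } else {
      out[fg, ] <- females[fg] * pm
    }
  }
  out
}

#' @export
print.gd_sim <- function(x, ...) {
  cat("<gd_sim> ", x$n_reps, " ", x$mode, " rep(s), ", x$days, " days\n", sep = "")
  if (nrow(x$release) > 0) {
    cat(sprintf("  release: %s %s x %d at day %d\n",
                x$release$genotype[1], x$release$sex[1],
                as.integer(x$release$count[1]), x$release$day[1]))
  }
  invisible(x)
}

#' Tidy a simulation into a long trajectory table
#'
#' @param x A `gd_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `rep`, `day`, `stage` (`adult_female`,
#'   `adult_male`, `aquatic`), `genotype`, `count`.
#' @method tidy gd_sim
#' @export
tidy.gd_sim <- function(x, ...) {
  gt <- x$genotypes
  purrr::imap_dfr(x$reps, function(r, rep_i) {
    purrr::imap_dfr(
      list(adult_female = r$f, adult_male = r$m, aquatic = r$aq),
      function(m, stage) {
        tibble(
          rep = rep_i, day = rep(seq_len(nrow(m)), times = 6),
          stage = stage, genotype = rep(gt, each = nrow(m)),
          count = as.vector(m)
        )
      }
    )
  })
}

#' Drive-carrier coverage among adult females
#'
#' The fraction of adult females whose genotype contains at least one drive
#' (`H`) allele -- the proxy for carrying a linked antiviral effector. The
#' coverage is 0 on days with no females.
#'
#' @param sim A `gd_sim` object.
#' @return A tibble with `rep`, `day`, `days_pr` (days post-release) and
#'   `coverage`.
#' @export
effector_coverage <- function(sim) {
  h_idx <- which(h_dosage() > 0)
  purrr::imap_dfr(sim$reps, function(r, rep_i) {
    tot <- rowSums(r$f)
    cov <- ifelse(tot > 0, rowSums(r$f[, h_idx, drop = FALSE]) / tot, 0)
    tibble(
      rep = rep_i, day = seq_along(cov),
      days_pr = seq_along(cov) - sim$release_day, coverage = cov
    )
  })
}
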