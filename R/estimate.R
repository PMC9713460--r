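# Drive-parameter estimation from single-generation cross observations.

#' Estimate germline cutting and homing rates from pooled cross counts
#'
#' Reproduces the pooled-count arithmetic used to turn marker-inheritance
#' tables into cube parameters. For each `line` x `parent_sex` group the
#' "low" and "high" pools are combined:
#'
#' * marker-positive offspring `P` = sum over pools of the marker-positive
#'   count (reconstructed as `round(marker_rate * n_assessed)` when only a
#'   rate is printed);
#' * estimated GDBI carriers `G` = sum over pools of
#'   `(n_assessed - positives) * gdbi_positive / gdbi_tested`, i.e. the
#'   per-pool fraction of sequenced marker-negative larvae with
#'   drive-blocking indels, scaled to all marker-negatives of that pool
#'   (pools with no sequencing fall back to the pooled fraction across the
#'   group's tested pools);
#' * cutting rate `c = (P + G) / N`, homing resolution `ch = P / (P + G)`,
#'   resistance resolution `cr = 1 - ch` (with `ch = 1` when `G = 0`).
#'
#' @param pools A data frame with one row per pool and columns `line`,
#'   `parent_sex` (`"F"`/`"M"`), `n_assessed`, `gdbi_tested`,
#'   `gdbi_positive`, and either `marker_positive` (raw counts, used as-is)
#'   or `marker_rate` (fraction in `[0, 1]`; counts are reconstructed by
#'   rounding). An optional `pool` label column is carried through
#'   diagnostics.
#' @return A tibble with one row per `line` x `parent_sex`:
#'   `n_total`, `n_marker_positive`, `n_gdbi_est`, `c`, `ch`, `cr`.
#' @export
#' @examples
#' pools <- tibble::tibble(
#'   line = "nos", parent_sex = "M", pool = c("low", "high"),
#'   marker_rate = c(0.553, 0.864), n_assessed = c(228, 214),
#'   gdbi_tested = c(54, 27), gdbi_positive = c(9, 7)
#' )
#' estimate_cut_params(pools)
estimate_cut_params <- function(pools) {
  pools <- as_tibble(pools)
  need <- c("line", "parent_sex", "n_assessed", "gdbi_tested", "gdbi_positive")
  missing_cols <- setdiff(need, names(pools))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "estimate_cut_params: missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!("marker_positive" %in% names(pools)) &&
      !("marker_rate" %in% names(pools))) {
    abort("estimate_cut_params: need either `marker_positive` or `marker_rate`")
  }
  if (nrow(pools) == 0 || all(pools$n_assessed <= 0)) {
    abort("estimate_cut_params: no pools with n_assessed > 0")
  }
  if (any(pools$gdbi_positive > pools$gdbi_tested)) {
    abort("estimate_cut_params: gdbi_positive exceeds gdbi_tested")
  }

  if (!("marker_positive" %in% names(pools))) {
    if (any(pools$marker_rate < 0 | pools$marker_rate > 1, na.rm = TRUE)) {
      abort("estimate_cut_params: marker_rate must be in [0, 1]")
    }
    pools$marker_positive <- round(pools$marker_rate * pools$n_assessed)
  }
  if (any(pools$marker_positive > pools$n_assessed)) {
    abort("estimate_cut_params: marker_positive exceeds n_assessed")
  }

  pools %>%
    group_by(.data$line, .data$parent_sex) %>%
    dplyr::group_modify(~ estimate_cut_one(.x)) %>%
    ungroup()
}

estimate_cut_one <- function(df) {
  df <- df[df$n_assessed > 0, , drop = FALSE]
  if (nrow(df) == 0) abort("estimate_cut_params: all-zero counts in a group")
  negatives <- df$n_assessed - df$marker_positive
  tested <- df$gdbi_tested
  frac <- ifelse(tested > 0, df$gdbi_positive / tested, NA_real_)
  if (all(is.na(frac)) && any(negatives > 0)) {
    # no pool sequenced at all: treat GDBI as unobserved (zero), the
    # conservative analogue of the zero-positive branch
    frac[is.na(frac)] <- 0
  } else if (any(is.na(frac))) {
    pooled <- sum(df$gdbi_positive) / sum(tested)
    frac[is.na(frac)] <- pooled
  }
  P <- sum(df$marker_positive)
  G <- sum(negatives * frac)
  N <- sum(df$n_assessed)
  if (P + G <= 0) abort("estimate_cut_params: no marker-positive or GDBI-positive offspring")
  ch <- P / (P + G)
  tibble(
    n_total = N,
    n_marker_positive = P,
    n_gdbi_est = G,
    c = (P + G) / N,
    ch = ch,
    cr = 1 - ch
  )
}

#' Estimate the maternal deposition rate from a trans-heterozygous assay
#'
#' In the balancer design the mother is a trans-heterozygote carrying the
#' drive over a blocked-drive (eCFP-marked) allele and is outcrossed to
#' wild-type males. Offspring inheriting the eCFP allele carry no drive, so
#' any cutting of their (editable, paternally inherited) wild-type allele at
#' the drive locus must come from maternally deposited Cas9-RNP. The
#' deposition rate `dF` is the mean over replicates of the per-replicate
#' fraction of eCFP-class larvae with activity at the drive locus. The
#' deposition resolution is fixed at `dhF = 0`, `drF = 1` (no homology
#' template in the embryo).
#'
#' @param assay A data frame with one row per replicate and columns
#'   `marker_class` (`"eCFP"`/`"mCherry"`), `n_larvae` and
#'   `n_active_drive_locus` (larvae with Cas9 activity at the drive locus).
#' @return A one-row tibble with `dF`, `dhF`, `drF`, `n_replicates`.
#' @export
#' @examples
#' assay <- tibble::tibble(
#'   marker_class = "eCFP", n_larvae = c(10, 10, 10),
#'   n_active_drive_locus = c(2, 4, 3)
#' )
#' estimate_deposition(assay)  # dF = 0.30
estimate_deposition <- function(assay) {
  assay <- as_tibble(assay)
  need <- c("marker_class", "n_larvae", "n_active_drive_locus")
  missing_cols <- setdiff(need, names(assay))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "estimate_deposition: missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  ecfp <- assay[assay$marker_class == "eCFP" & assay$n_larvae > 0, , drop = FALSE]
  if (nrow(ecfp) == 0) {
    abort("estimate_deposition: no eCFP-class replicates with larvae")
  }
  if (any(ecfp$n_active_drive_locus > ecfp$n_larvae)) {
    abort("estimate_deposition: activity counts exceed larvae counts")
  }
  tibble(
    dF = mean(ecfp$n_active_drive_locus / ecfp$n_larvae),
    dhF = 0,
    drF = 1,
    n_replicates = nrow(ecfp)
  )
}

#' Derive lifecycle and fitness-modifier parameters from a fitness table
#'
#' Converts line-level life-parameter summaries into simulation inputs:
#'
#' * `betaK` (eggs/female/day) = mean fecundity per gonotrophic cycle x 4
#'   blood meals over a female lifetime / 11 days average urban lifespan;
#' * `tLarva` = mean larva-to-pupa development time, rounded to whole days;
#' * `xiF`/`xiM` (pupation-success multiplier for drive carriers) =
#'   `1 + (viability(line) - viability(reference))` when the deficit is
#'   negative and flagged significant, else 1 (no modifier);
#' * `fertility_mult` = 0.9 for drive-carrying genotypes (the assumed 10%
#'   fertility reduction), 1 otherwise.
#'
#' Significance gating is taken from the `viability_significant` flag rather
#' than re-testing, so callers control which contrasts count.
#'
#' @param fitness A data frame with columns `line`, `fecundity_mean`,
#'   `larval_viability`, `larva_to_pupa_days` and logical
#'   `viability_significant`.
#' @param line Drive line to derive parameters for.
#' @param reference_line Wild-type comparison line.
#' @return A one-row tibble with `line`, `betaK`, `tLarva`, `xiF`, `xiM`,
#'   `fertility_mult`.
#' @export
#' @examples
#' fit <- tibble::tibble(
#'   line = c("wt", "gd"), fecundity_mean = c(76, 75),
#'   larval_viability = c(0.80, 0.70), larva_to_pupa_days = c(6.1, 6.3),
#'   viability_significant = c(NA, TRUE)
#' )
#' derive_lifecycle(fit, "gd", "wt")
derive_lifecycle <- function(fitness, line, reference_line) {
  fitness <- as_tibble(fitness)
  need <- c("line", "fecundity_mean", "larval_viability", "larva_to_pupa_days")
  missing_cols <- setdiff(need, names(fitness))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "derive_lifecycle: missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  row <- fitness[fitness$line == line, , drop = FALSE]
  ref <- fitness[fitness$line == reference_line, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("derive_lifecycle: line not found: ", line))
  if (nrow(ref) != 1) {
    abort(paste0("derive_lifecycle: reference line not found: ", reference_line))
  }
  delta <- row$larval_viability - ref$larval_viability
  significant <- isTRUE(row$viability_significant)
  xi <- if (delta < 0 && significant) 1 + delta else 1
  tibble(
    line = line,
    betaK = row$fecundity_mean * 4 / 11,
    tLarva = as.integer(round(row$larva_to_pupa_days)),
    xiF = xi,
    xiM = xi,
    fertility_mult = 0.9
  )
}

#' Assemble drive parameters from estimation outputs
#'
#' Convenience constructor combining the per-sex cutting estimates of
#' [estimate_cut_params()], the deposition estimate of
#' [estimate_deposition()] (or a printed rate), and the fitness modifiers of
#' [derive_lifecycle()] into a single [drive_params()] object.
#'
#' @param cut_params Tibble from [estimate_cut_params()], containing one
#'   `"F"` and one `"M"` row for the chosen line.
#' @param dF Maternal deposition rate (scalar, or a tibble from
#'   [estimate_deposition()]).
#' @param lifecycle Optional one-row tibble from [derive_lifecycle()]
#'   supplying `xiF`, `xiM`, `fertility_mult`.
#' @param line Line to select when `cut_params` holds several.
#' @return A [drive_params()] object.
#' @export
as_drive_params <- function(cut_params, dF = 0, lifecycle = NULL, line = NULL) {
  cp <- as_tibble(cut_params)
  if (!is.null(line)) cp <- cp[cp$line == line, , drop = FALSE]
  fr <- cp[cp$parent_sex == "F", , drop = FALSE]
  mr <- cp[cp$parent_sex == "M", , drop = FALSE]
  if (nrow(fr) != 1 || nrow(mr) != 1) {
    abort("as_drive_params: need exactly one female and one male estimate row")
  }
  if (is.data.frame(dF)) dF <- dF$dF[1]
  fert <- if (!is.null(lifecycle)) lifecycle$fertility_mult[1] else 1
  xiF <- if (!is.null(lifecycle)) lifecycle$xiF[1] else 1
  xiM <- if (!is.null(lifecycle)) lifecycle$xiM[1] else 1
  drive_params(
    cF = fr$c, chF = fr$ch, crF = fr$cr,
    cM = mr$c, chM = mr$ch, crM = mr$cr,
    dF = dF, dhF = 0, drF = 1,
    fertility_mult = fert, xiF = xiF, xiM = xiM
  )
}
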