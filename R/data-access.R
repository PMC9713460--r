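# Accessors for the small plain-text datasets shipped with the package.

drivesim_extdata <- function(file) {
  path <- system.file("extdata", file, package = "drivesim")
  if (path == "") abort(paste0("packaged dataset not found: ", file))
  path
}

#' Packaged study datasets
#'
#' Small tables shipped with the package:
#'
#' * `ox1_pool_counts()`: pooled first-outcross (OX-1) marker-inheritance
#'   and GDBI assay counts per drive line, parent sex and low/high pool --
#'   the input to [estimate_cut_params()]. Marker-positive counts are given
#'   as the printed inheritance rates (`marker_rate`) with the pool sizes.
#' * `transhet_genotype_counts()`: replicate-level genotype counts of the
#'   surviving larvae from the trans-heterozygous maternal-contribution
#'   injections (eCFP vs mCherry class per replicate).
#' * `deposition_activity()`: the reported mean Cas9 activity rates among
#'   eCFP-class larvae at the drive locus (used directly as the maternal
#'   deposition rate `dF`) and at the sgRNA-injected secondary locus.
#' * `line_fitness_synthetic()`: a synthetic stand-in for the unpublished
#'   life-parameter summaries (fecundity, larval viability, larva-to-pupa
#'   days); values are package defaults chosen to be realistic for
#'   laboratory *Ae. aegypti*, with the drive line's larval-viability
#'   deficit of 0.10 flagged significant. See the methods vignette.
#' * `injection_survival_counts()`: embryo-injection survivor counts per
#'   transgenic line.
#'
#' @return A tibble.
#' @export
ox1_pool_counts <- function() {
  as_tibble(utils::read.csv(drivesim_extdata("ox1_pools.csv"),
                            stringsAsFactors = FALSE))
}

#' @rdname ox1_pool_counts
#' @export
transhet_genotype_counts <- function() {
  as_tibble(utils::read.csv(drivesim_extdata("transhet_genotypes.csv"),
                            stringsAsFactors = FALSE))
}

#' @rdname ox1_pool_counts
#' @export
deposition_activity <- function() {
  as_tibble(utils::read.csv(drivesim_extdata("deposition_activity.csv"),
                            stringsAsFactors = FALSE))
}

#' @rdname ox1_pool_counts
#' @export
line_fitness_synthetic <- function() {
  as_tibble(utils::read.csv(drivesim_extdata("fitness_synthetic.csv"),
                            stringsAsFactors = FALSE))
}

#' @rdname ox1_pool_counts
#' @export
injection_survival_counts <- function() {
  as_tibble(utils::read.csv(drivesim_extdata("injection_survival.csv"),
                            stringsAsFactors = FALSE))
}

#' Study drive-parameter sets for the two modelled lines
#'
#' Derives the full [drive_params()] configuration of a modelled line from
#' the packaged datasets: per-sex cutting/homing/resistance rates from the
#' pooled OX-1 counts, the maternal deposition rate from the reported
#' eCFP-class drive-locus activity, and fitness modifiers from the packaged
#' fitness table (pupation modifier only where the larval-viability deficit
#' is flagged significant; 10% fertility reduction for both lines).
#'
#' @param line `"AeaNosC109"` or `"AeaZpgC109"`.
#' @param reference_line Wild-type comparison line in the fitness table.
#' @return A list with `params` ([drive_params()]), `lifecycle`
#'   ([lifecycle_params()] with the line's `betaK` and `tLarva`), and the
#'   intermediate `cut_params`, `dF`, `lifecycle_row` tibbles.
#' @export
#' @examples
#' line_config("AeaZpgC109")$params
line_config <- function(line = c("AeaNosC109", "AeaZpgC109"),
                        reference_line = "HWE") {
  line <- match.arg(line)
  cuts <- estimate_cut_params(
    ox1_pool_counts() %>% filter(.data$line == !!line)
  )
  dep <- deposition_activity()
  dF <- dep$activity_rate[dep$line == line & dep$locus == "drive_locus"][1]
  fit <- line_fitness_synthetic()
  lc_row <- derive_lifecycle(fit, line, reference_line)
  params <- as_drive_params(cuts, dF = dF, lifecycle = lc_row, line = line)
  lc <- lifecycle_params(betaK = lc_row$betaK, tLarva = lc_row$tLarva)
  list(params = params, lifecycle = lc, cut_params = cuts, dF = dF,
       lifecycle_row = lc_row)
}
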