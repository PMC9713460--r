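# Allele and genotype state space.
#
# The population model tracks three alleles at the drive locus:
#   W  wild-type (cleavable protospacer present)
#   H  homing gene drive (Cas9 + sgRNA + marker cassette)
#   R  drive-blocking resistance allele (GDBI); cost-free, merged from the
#      no-cost and costly resistance classes
# A fourth allele, E (the eCFP-marked "blocked drive" balancer), exists only
# in the cross-synthesis layer: its insertion destroys the protospacer, so it
# is uncleavable and inert, and it never appears on an inheritance-cube axis.

#' Alleles and genotypes of the drive locus
#'
#' `drive_alleles()` returns the three population-model allele codes in
#' canonical order; `drive_genotypes()` returns the six unordered diploid
#' genotypes built from them, in the fixed order used on every inheritance
#' cube axis.
#'
#' @return A character vector.
#' @export
#' @examples
#' drive_alleles()
#' drive_genotypes()
drive_alleles <- function() c("W", "H", "R")

#' @rdname drive_alleles
#' @export
drive_genotypes <- function() c("WW", "WH", "WR", "HH", "HR", "RR")

#' Collapse an allele pair to its canonical unordered genotype
#'
#' Genotypes are unordered (no parent-of-origin tracking beyond the maternal
#' deposition step), so `WH` and `HW` are the same state. Alleles are ordered
#' `W < H < R`.
#'
#' @param a1,a2 Allele codes (`"W"`, `"H"` or `"R"`); vectorised.
#' @return Character vector of genotype codes.
#' @export
#' @examples
#' canonical_genotype("H", "W")  # "WH"
canonical_genotype <- function(a1, a2) {
  ord <- c(W = 1L, H = 2L, R = 3L)
  if (any(!a1 %in% names(ord)) || any(!a2 %in% names(ord))) {
    abort("alleles must be one of 'W', 'H', 'R'")
  }
  swap <- ord[a1] > ord[a2]
  first <- ifelse(swap, a2, a1)
  second <- ifelse(swap, a1, a2)
  paste0(first, second)
}

genotype_alleles <- function(genotype) {
  gt <- drive_genotypes()
  if (any(!genotype %in% gt)) {
    abort(paste0(
      "unknown genotype: ",
      paste(setdiff(genotype, gt), collapse = ", "),
      " (expected one of ", paste(gt, collapse = ", "), ")"
    ))
  }
  lapply(strsplit(genotype, ""), identity)
}

# Genotypes carrying at least one drive allele; used for fitness modifiers
# and effector-coverage summaries.
h_carrier_genotypes <- function() c("WH", "HH", "HR")

#' Drive-locus rate and fitness parameters
#'
#' Bundles every cube-level rate of the homing model together with the
#' fitness modifiers applied in the population simulation.
#'
#' Germline cutting acts only on `W` alleles in genotypes that also carry an
#' `H` allele (the cassette carries both Cas9 and the sgRNA). A cut `W` is
#' resolved either by homology-directed repair into `H` ("homing") or by
#' end-joining into the cost-free resistance allele `R` (a
#' gene-drive-blocking indel, GDBI). Maternal deposition of Cas9
#' ribonucleoprotein acts after fertilisation: when the mother carries `H`,
#' each `W` allele of the zygote is cut with probability `dF` and resolved
#' into `H` with probability `dhF` or `R` with probability `drF`
#' (embryos lack a homology template, so the measured configuration is
#' `dhF = 0`, `drF = 1`).
#'
#' @param cF,cM Probability that a `W` allele in an `H`-carrying germline is
#'   cut (female / male parent).
#' @param chF,chM Probability that a germline cut is resolved by homing
#'   (conversion to `H`).
#' @param crF,crM Probability that a germline cut is resolved as resistance
#'   (conversion to `R`); must satisfy `chF + crF = 1` and `chM + crM = 1`.
#' @param dF Probability that a zygotic `W` allele from an `H`-carrying
#'   mother is cut by deposited Cas9-RNP.
#' @param dhF,drF Split of deposition outcomes into `H` / `R`; must sum to 1.
#' @param fertility_mult Fecundity multiplier applied to `H`-carrying
#'   genotypes (dimensionless; 0.9 models a 10% fertility reduction).
#' @param xiF,xiM Pupation-success multiplier applied to `H`-carrying
#'   genotypes per sex (dimensionless; 1 means no cost).
#' @return An object of class `drive_params` (a validated named list).
#' @export
#' @examples
#' drive_params(cF = 0.759, chF = 0.927, dF = 0.19)
drive_params <- function(cF = 0, cM = 0, chF = 1, chM = 1,
                         crF = 1 - chF, crM = 1 - chM,
                         dF = 0, dhF = 0, drF = 1 - dhF,
                         fertility_mult = 1, xiF = 1, xiM = 1) {
  p <- list(
    cF = cF, cM = cM, chF = chF, chM = chM, crF = crF, crM = crM,
    dF = dF, dhF = dhF, drF = drF,
    fertility_mult = fertility_mult, xiF = xiF, xiM = xiM
  )
  class(p) <- "drive_params"
  validate_drive_params(p)
  p
}

validate_drive_params <- function(p) {
  probs <- c("cF", "cM", "chF", "chM", "crF", "crM", "dF", "dhF", "drF")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < -1e-12 || v > 1 + 1e-12) {
      abort(paste0("drive_params: `", nm, "` must be a probability in [0, 1]"))
    }
  }
  if (abs(p$chF + p$crF - 1) > 1e-9 || abs(p$chM + p$crM - 1) > 1e-9) {
    abort("drive_params: cut resolution must satisfy chF + crF = 1 and chM + crM = 1")
  }
  if (abs(p$dhF + p$drF - 1) > 1e-9) {
    abort("drive_params: deposition resolution must satisfy dhF + drF = 1")
  }
  for (nm in c("fertility_mult", "xiF", "xiM")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort(paste0("drive_params: `", nm, "` must be a non-negative scalar"))
    }
  }
  invisible(p)
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params>\n")
  cat(sprintf("  germline  F: c = %.4f, ch = %.4f, cr = %.4f\n", x$cF, x$chF, x$crF))
  cat(sprintf("            M: c = %.4f, ch = %.4f, cr = %.4f\n", x$cM, x$chM, x$crM))
  cat(sprintf("  deposition: dF = %.4f (dhF = %.2f, drF = %.2f)\n", x$dF, x$dhF, x$drF))
  cat(sprintf(
    "  fitness   : fertility x%.2f, pupation xiF %.2f / xiM %.2f (H carriers)\n",
    x$fertility_mult, x$xiF, x$xiM
  ))
  invisible(x)
}
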