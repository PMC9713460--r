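# Inheritance cube: mother genotype x father genotype x offspring genotype
# probability tensor over the six drive-locus genotypes.

#' Germline gamete allele distribution of a parent
#'
#' Returns the probability distribution over transmitted alleles for a parent
#' of the given genotype and sex. Each of the two alleles is transmitted with
#' probability 1/2; a transmitted `W` allele is additionally cut in the
#' germline (only if the genotype also carries `H`) with the sex-specific
#' probability `c`, and a cut resolves to `H` (homing) with probability `ch`
#' or to `R` (resistance) with probability `cr`.
#'
#' For a `WH` parent of sex *s* this gives
#' `P(H) = 1/2 + 1/2 c_s ch_s`, `P(W) = 1/2 (1 - c_s)`,
#' `P(R) = 1/2 c_s cr_s`; all other genotypes segregate Mendelian.
#'
#' @param genotype One of `drive_genotypes()`.
#' @param parent_sex `"F"` or `"M"`.
#' @param params A [drive_params()] object.
#' @return Named numeric vector over `c("W", "H", "R")`, summing to 1.
#' @export
#' @examples
#' gamete_distribution("WH", "M", drive_params(cM = 0.759, chM = 0.927))
gamete_distribution <- function(genotype, parent_sex, params) {
  validate_drive_params(params)
  parent_sex <- match.arg(parent_sex, c("F", "M"))
  alleles <- genotype_alleles(genotype)[[1]]
  c_s <- if (parent_sex == "F") params$cF else params$cM
  ch_s <- if (parent_sex == "F") params$chF else params$chM
  cr_s <- if (parent_sex == "F") params$crF else params$crM
  has_h <- "H" %in% alleles

  out <- c(W = 0, H = 0, R = 0)
  for (a in alleles) {
    if (a == "W" && has_h) {
      out["W"] <- out["W"] + 0.5 * (1 - c_s)
      out["H"] <- out["H"] + 0.5 * c_s * ch_s
      out["R"] <- out["R"] + 0.5 * c_s * cr_s
    } else {
      out[a] <- out[a] + 0.5
    }
  }
  out
}

# Deposition kernel: distribution of a single zygotic allele after maternal
# Cas9-RNP exposure. Only W alleles are cleavable.
deposition_outcomes <- function(allele, params) {
  if (allele != "W") {
    return(setNames(1, allele))
  }
  c(
    W = 1 - params$dF,
    H = params$dF * params$dhF,
    R = params$dF * params$drF
  )
}

#' Offspring genotype distribution of a single cross
#'
#' Combines the maternal (sex `F`) and paternal (sex `M`) gamete
#' distributions by random union, then applies maternal deposition: when the
#' mother's genotype carries at least one `H` allele, each `W` allele of the
#' zygote -- regardless of parental origin -- is independently cut by
#' deposited Cas9-RNP with probability `dF` and resolved into `H`
#' (probability `dhF`) or `R` (probability `drF`).
#'
#' Deposition on the maternally inherited `W` is a modelled generalisation:
#' the underlying assay measures deposition on the paternal allele only, but
#' deposited RNP in the embryo has no way to distinguish allele origin.
#'
#' @inheritParams gamete_distribution
#' @param mother,father Parental genotypes, from `drive_genotypes()`.
#' @return Named numeric vector over `drive_genotypes()`, summing to 1.
#' @export
#' @examples
#' zygote_distribution("WH", "WW", drive_params(cF = 0.759, chF = 0.927, dF = 0.19))
zygote_distribution <- function(mother, father, params) {
  gm <- gamete_distribution(mother, "F", params)
  gf <- gamete_distribution(father, "M", params)
  mother_has_h <- "H" %in% genotype_alleles(mother)[[1]]

  out <- setNames(numeric(6), drive_genotypes())
  for (am in names(gm)) {
    if (gm[[am]] == 0) next
    for (af in names(gf)) {
      p_union <- gm[[am]] * gf[[af]]
      if (p_union == 0) next
      if (mother_has_h) {
        dm <- deposition_outcomes(am, params)
        df <- deposition_outcomes(af, params)
        for (bm in names(dm)) {
          for (bf in names(df)) {
            p <- p_union * dm[[bm]] * df[[bf]]
            if (p == 0) next
            g <- canonical_genotype(bm, bf)
            out[g] <- out[g] + p
          }
        }
      } else {
        g <- canonical_genotype(am, af)
        out[g] <- out[g] + p_union
      }
    }
  }
  out
}

#' Build the homing inheritance cube
#'
#' Assembles the full mother-genotype x father-genotype x offspring-genotype
#' probability tensor by evaluating [zygote_distribution()] for all 36 parent
#' pairs. Every `(mother, father)` slice is a probability distribution over
#' the six offspring genotypes.
#'
#' @param params A [drive_params()] object.
#' @return An `inheritance_cube`: a 6 x 6 x 6 array with dimnames
#'   `mother`, `father`, `offspring`, carrying the generating `params` as an
#'   attribute.
#' @export
#' @examples
#' cube <- build_cube(drive_params(cF = 0.76, chF = 0.93, dF = 0.19))
#' cube["WH", "WW", ]
build_cube <- function(params) {
  validate_drive_params(params)
  gt <- drive_genotypes()
  probs <- array(
    0, dim = c(6, 6, 6),
    dimnames = list(mother = gt, father = gt, offspring = gt)
  )
  for (m in gt) {
    for (f in gt) {
      probs[m, f, ] <- zygote_distribution(m, f, params)
    }
  }
  structure(probs, class = c("inheritance_cube", "array"), params = params)
}

#' Mendelian inheritance cube
#'
#' The no-drive limit: random union of gametes over `{W, H, R}` with no
#' cutting and no deposition. Serves as the neutral reference for the homing
#' cube.
#'
#' @return An `inheritance_cube`.
#' @export
#' @examples
#' mendelian_cube()["WH", "WH", ]  # 1/4, 1/2, 1/4 over WW, WH, HH
mendelian_cube <- function() {
  build_cube(drive_params())
}

#' @export
print.inheritance_cube <- function(x, ...) {
  cat("<inheritance_cube> 6 x 6 x 6 (mother x father x offspring)\n")
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat(sprintf(
      "  cF = %.3f chF = %.3f | cM = %.3f chM = %.3f | dF = %.3f\n",
      p$cF, p$chF, p$cM, p$chM, p$dF
    ))
  }
  cat("  WH x WW row:\n")
  print(round(x["WH", "WW", ], 5))
  invisible(x)
}

#' Tidy an inheritance cube into a long tibble
#'
#' @param x An `inheritance_cube`.
#' @param ... Unused.
#' @return A tibble with columns `mother`, `father`, `offspring`,
#'   `probability` (216 rows, canonical genotype order).
#' @method tidy inheritance_cube
#' @export
tidy.inheritance_cube <- function(x, ...) {
  gt <- drive_genotypes()
  grid <- tidyr::expand_grid(mother = gt, father = gt, offspring = gt)
  grid$probability <- purrr::pmap_dbl(
    grid,
    function(mother, father, offspring) x[mother, father, offspring]
  )
  grid
}

#' Read and write inheritance cubes as CSV
#'
#' The on-disk form is the long table `mother, father, offspring,
#' probability` in canonical genotype order, probabilities at full double
#' precision (15 significant digits).
#'
#' @param cube An `inheritance_cube`.
#' @param path File path.
#' @return `write_cube_csv()` returns `path` invisibly; `read_cube_csv()`
#'   returns an `inheritance_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  df <- tidy.inheritance_cube(cube)
  df$probability <- formatC(df$probability, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mother", "father", "offspring", "probability")
  if (!all(need %in% names(df))) {
    abort(paste0(
      "cube CSV must have columns ", paste(need, collapse = ", "),
      "; missing: ", paste(setdiff(need, names(df)), collapse = ", ")
    ))
  }
  gt <- drive_genotypes()
  probs <- array(
    0, dim = c(6, 6, 6),
    dimnames = list(mother = gt, father = gt, offspring = gt)
  )
  for (i in seq_len(nrow(df))) {
    probs[df$mother[i], df$father[i], df$offspring[i]] <- df$probability[i]
  }
  validate_cube(structure(probs, class = c("inheritance_cube", "array")))
}

validate_cube <- function(cube, tol = 1e-12) {
  if (any(cube < -tol)) abort("inheritance cube has negative entries")
  sums <- apply(cube, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("inheritance cube rows do not sum to 1")
  }
  cube
}
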