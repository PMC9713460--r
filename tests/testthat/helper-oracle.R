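# Independent brute-force oracle for the homing inheritance model.
#
# Enumerates the full event tree (allele choice -> germline cut -> cut
# resolution -> per-allele deposition) as an explicit path table with joint
# probabilities, rather than composing distributions the way the package
# does. Used to cross-check gamete/zygote/cube calculations.

oracle_gametes <- function(genotype, sex, params) {
  alleles <- strsplit(genotype, "")[[1]]
  has_h <- "H" %in% alleles
  c_s <- if (sex == "F") params$cF else params$cM
  ch_s <- if (sex == "F") params$chF else params$chM
  paths <- expand.grid(
    idx = 1:2, cut = c(TRUE, FALSE), res = c("H", "R"),
    stringsAsFactors = FALSE
  )
  out <- c(W = 0, H = 0, R = 0)
  for (k in seq_len(nrow(paths))) {
    a <- alleles[paths$idx[k]]
    cleavable <- a == "W" && has_h
    p_cut <- if (cleavable) {
      if (paths$cut[k]) c_s else 1 - c_s
    } else {
      if (paths$cut[k]) 0 else 1
    }
    p_res <- if (paths$cut[k]) {
      if (paths$res[k] == "H") ch_s else 1 - ch_s
    } else 0.5  # resolution branch vacuous when no cut; split to keep sum 1
    outcome <- if (paths$cut[k]) paths$res[k] else a
    out[outcome] <- out[outcome] + 0.5 * p_cut * p_res
  }
  out
}

oracle_deposit <- function(allele, mother_has_h, params) {
  if (!mother_has_h || allele != "W") {
    return(setNames(1, allele))
  }
  c(W = 1 - params$dF, H = params$dF * params$dhF, R = params$dF * params$drF)
}

oracle_canonical <- function(a1, a2) {
  lev <- c("W", "H", "R")
  paste(sort(factor(c(a1, a2), levels = lev)), collapse = "")
}

oracle_zygote <- function(mother, father, params) {
  gm <- oracle_gametes(mother, "F", params)
  gf <- oracle_gametes(father, "M", params)
  mh <- "H" %in% strsplit(mother, "")[[1]]
  out <- setNames(numeric(6), drive_genotypes())
  for (am in names(gm)) for (af in names(gf)) {
    dm <- oracle_deposit(am, mh, params)
    df <- oracle_deposit(af, mh, params)
    for (bm in names(dm)) for (bf in names(df)) {
      p <- gm[[am]] * gf[[af]] * dm[[bm]] * df[[bf]]
      if (p > 0) {
        g <- oracle_canonical(bm, bf)
        out[g] <- out[g] + p
      }
    }
  }
  out
}

oracle_cube <- function(params) {
  gt <- drive_genotypes()
  arr <- array(0, dim = c(6, 6, 6), dimnames = list(gt, gt, gt))
  for (m in gt) for (f in gt) arr[m, f, ] <- oracle_zygote(m, f, params)
  arr
}

random_drive_params <- function() {
  chF <- runif(1)
  chM <- runif(1)
  dhF <- runif(1)
  drive_params(
    cF = runif(1), cM = runif(1), chF = chF, chM = chM,
    crF = 1 - chF, crM = 1 - chM,
    dF = runif(1), dhF = dhF, drF = 1 - dhF
  )
}
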