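# Synthetic-data generators emulating the statistical structure of the
# cross, deposition and amplicon observations, so every analysis stage is
# testable without external data.

#' Synthesize a hemizygote x wild-type cross dataset
#'
#' Generates family-level offspring counts for the standard drive-activity
#' design: hemizygous (`WH`) parents of one sex outcrossed to wild-type
#' (`WW`). Offspring genotypes are drawn multinomially from the inheritance
#' cube row of the cross (`WH` mother x `WW` father for female parentals;
#' `WW` mother x `WH` father for male parentals), so germline cutting,
#' homing, resistance formation and (for female parentals) maternal
#' deposition all act. Marker-positive offspring are the drive carriers; a
#' GDBI assay subsamples the marker-negative offspring and scores carriers
#' of at least one `R` allele as indel-positive (sequence-level indels are
#' identified one-to-one with `R` alleles).
#'
#' Family sizes are drawn from a negative binomial truncated to
#' `[size_min, size_max]`, matching the observed per-family larval count
#' ranges (roughly 20-142 at mean 59 for female parentals, 21-415 at mean
#' 91 for male parentals).
#'
#' Two generative models are available because the pooled estimation
#' arithmetic and the inheritance cube use different parameter scales (see
#' the methods vignette). Under `transmission = "cube"` (default) offspring
#' follow the population model exactly: marker inheritance is
#' `(1 + c ch) / 2`, so Mendelian segregation corresponds to `c = 0` -- but
#' [estimate_cut_params()] applied to such data returns `(1 + c)/2`, not
#' `c`, because the pooled arithmetic attributes every marker-positive
#' offspring to a cutting event. Under `transmission = "estimation"` the
#' hemizygote parent transmits `H` with probability `c ch`, `R` with
#' probability `c cr` and `W` with probability `1 - c` (and no embryonic
#' deposition acts), the model under which the pooled arithmetic is exactly
#' unbiased; Mendelian segregation then corresponds to `c = 0.5, ch = 1`.
#'
#' @param params True [drive_params()].
#' @param transmission `"cube"` (population-model semantics) or
#'   `"estimation"` (estimator-consistent semantics; see Details).
#' @param n_families Families per parent sex.
#' @param parent_sex Sexes to generate (default both).
#' @param size_mean,size_min,size_max Family-size distribution per parent
#'   sex (recycled; defaults mirror the observed ranges).
#' @param gdbi_test_fraction Fraction of marker-negative offspring subjected
#'   to the GDBI assay.
#' @param seed Integer seed.
#' @return A list with `families` (per-family records: `line`, `parent_sex`,
#'   `pool_label`, `n_offspring`, `n_marker_positive`, GDBI assay counts)
#'   and `pools` (the pooled low/high table consumed by
#'   [estimate_cut_params()]).
#' @export
#' @examples
#' synth <- synth_cross_dataset(drive_params(cF = 0.76, chF = 0.93),
#'                              n_families = 10, seed = 1)
#' estimate_cut_params(synth$pools)
synth_cross_dataset <- function(params, n_families = 50,
                                parent_sex = c("F", "M"),
                                transmission = c("cube", "estimation"),
                                size_mean = c(59, 91),
                                size_min = c(20, 21),
                                size_max = c(142, 415),
                                gdbi_test_fraction = 0.5,
                                seed = NULL) {
  transmission <- match.arg(transmission)
  validate_drive_params(params)
  if (n_families < 1) abort("synth_cross_dataset: need at least one family")
  if (gdbi_test_fraction < 0 || gdbi_test_fraction > 1) {
    abort("synth_cross_dataset: gdbi_test_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  cube <- build_cube(params)
  gt <- drive_genotypes()
  nH <- allele_dosage("H")
  nR <- allele_dosage("R")

  size_mean <- rep(size_mean, length.out = length(parent_sex))
  size_min <- rep(size_min, length.out = length(parent_sex))
  size_max <- rep(size_max, length.out = length(parent_sex))

  fams <- purrr::imap_dfr(parent_sex, function(sex, i) {
    row <- if (transmission == "cube") {
      if (sex == "F") cube["WH", "WW", ] else cube["WW", "WH", ]
    } else {
      # estimator-consistent transmitted-allele model; offspring genotype is
      # the transmitted allele over the wild-type partner allele
      c_s <- if (sex == "F") params$cF else params$cM
      ch_s <- if (sex == "F") params$chF else params$chM
      setNames(
        c(1 - c_s, c_s * ch_s, c_s * (1 - ch_s), 0, 0, 0),
        drive_genotypes()
      )  # WW, WH, WR carry the transmitted W/H/R allele
    }
    sizes <- rtrunc_nbinom(n_families, size_mean[i], size_min[i], size_max[i])
    purrr::map_dfr(seq_len(n_families), function(j) {
      geno <- rmultinom(1L, sizes[j], row)[, 1]
      pos <- sum(geno[nH > 0])
      neg_r <- sum(geno[nH == 0 & nR > 0])
      neg <- sizes[j] - pos
      tested <- rbinom(1L, neg, gdbi_test_fraction)
      # the assay samples marker-negatives without replacement
      positive <- if (tested > 0) {
        sum(sample(rep(c(TRUE, FALSE), c(neg_r, neg - neg_r)))[seq_len(tested)])
      } else 0L
      tibble(
        line = "synthetic", parent_sex = sex, family = j,
        n_offspring = sizes[j], n_marker_positive = pos,
        gdbi_tested = tested, gdbi_positive = positive
      )
    })
  })

  pools <- fams %>%
    group_by(.data$line, .data$parent_sex) %>%
    mutate(pool = ifelse(
      .data$n_marker_positive / .data$n_offspring <=
        median(.data$n_marker_positive / .data$n_offspring),
      "low", "high"
    )) %>%
    group_by(.data$line, .data$parent_sex, .data$pool) %>%
    summarise(
      marker_positive = sum(.data$n_marker_positive),
      n_assessed = sum(.data$n_offspring),
      gdbi_tested = sum(.data$gdbi_tested),
      gdbi_positive = sum(.data$gdbi_positive),
      .groups = "drop"
    )

  list(families = fams, pools = pools)
}

# Negative binomial (dispersion `size` fixed at 8, a moderate overdispersion
# matching the printed spread) truncated to [lo, hi] by resampling.
rtrunc_nbinom <- function(n, mean, lo, hi, dispersion = 8) {
  if (lo > hi) abort("family-size bounds are inverted")
  if (lo == hi) return(rep(as.integer(lo), n))
  out <- integer(0)
  while (length(out) < n) {
    draw <- rnbinom(2L * n, size = dispersion, mu = mean)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Synthesize a trans-heterozygous deposition assay
#'
#' Emulates the balancer design: trans-heterozygous mothers (drive over
#' blocked-drive eCFP allele) outcrossed to wild-type males. Each offspring
#' inherits the eCFP or the drive (mCherry) allele with probability 1/2;
#' eCFP-class offspring carry an editable paternal wild-type allele whose
#' cut state is Bernoulli with the true deposition rate `dF`.
#'
#' @param params True [drive_params()] (supplies `dF`).
#' @param n_per_rep Larvae genotyped per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return A tibble consumable by [estimate_deposition()]: one row per
#'   replicate x marker class with `n_larvae` and `n_active_drive_locus`.
#' @export
#' @examples
#' assay <- synth_transhet(drive_params(dF = 0.19), n_per_rep = 300,
#'                         reps = 3, seed = 1)
#' estimate_deposition(assay)
synth_transhet <- function(params, n_per_rep = 25, reps = 3, seed = NULL) {
  validate_drive_params(params)
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(reps), function(r) {
    n_ecfp <- rbinom(1L, n_per_rep, 0.5)
    n_mcherry <- n_per_rep - n_ecfp
    tibble(
      rep = r,
      marker_class = c("eCFP", "mCherry"),
      n_larvae = c(n_ecfp, n_mcherry),
      n_active_drive_locus = c(rbinom(1L, n_ecfp, params$dF), NA_integer_)
    )
  })
}

#' Synthesize amplicon read classifications
#'
#' Classifies `n_reads` reads with true indel probability
#' `true_indel_fraction`; a nonzero `chimera_rate` then converts a fraction
#' of the remaining unmodified reads into apparent indel reads (template
#' switching between edited and unedited molecules during pooled PCR), so
#' the apparent proportion is inflated to
#' `true + chimera_rate * (1 - true)` in expectation and can exceed the 50%
#' hemizygous ceiling. Event sizes default to a deletion-dominated spectrum
#' (93% deletions) with sizes capped at 82 bp (deletions) / 60 bp
#' (insertions) and offsets within +/- 50 bp of the cut site.
#'
#' @param true_indel_fraction True per-read indel probability.
#' @param n_reads Total reads.
#' @param chimera_rate PCR-chimera artifact rate (default 0).
#' @param deletion_share,substitution_share Composition of true indel reads.
#' @param max_deletion_bp,max_insertion_bp,offset_sd_bp Size/position
#'   spectrum controls.
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return A classification tibble (see [read_amplicon_classes()]).
#' @export
#' @examples
#' amp <- synth_amplicons(0.3, n_reads = 5000, seed = 1)
#' indel_proportion(amp)
synth_amplicons <- function(true_indel_fraction, n_reads,
                            chimera_rate = 0, deletion_share = 0.93,
                            substitution_share = 0.02,
                            max_deletion_bp = 82, max_insertion_bp = 60,
                            offset_sd_bp = 12, sample_id = "synthetic",
                            seed = NULL) {
  if (n_reads <= 0) abort("synth_amplicons: n_reads must be positive")
  if (true_indel_fraction < 0 || true_indel_fraction > 1 ||
      chimera_rate < 0 || chimera_rate > 1) {
    abort("synth_amplicons: fractions must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_true <- rbinom(1L, n_reads, true_indel_fraction)
  n_chim <- rbinom(1L, n_reads - n_true, chimera_rate)
  n_indel <- n_true + n_chim
  n_unmod <- n_reads - n_indel

  classes <- if (n_indel > 0) {
    sample(
      c("deletion", "insertion", "substitution"), n_indel, replace = TRUE,
      prob = c(deletion_share, 1 - deletion_share - substitution_share,
               substitution_share)
    )
  } else character(0)
  sizes <- vapply(classes, function(cl) {
    switch(cl,
      deletion = sample.int(max_deletion_bp, 1L, prob = exp(-(1:max_deletion_bp) / 8)),
      insertion = sample.int(max_insertion_bp, 1L, prob = exp(-(1:max_insertion_bp) / 5)),
      substitution = 1L
    )
  }, integer(1))
  offsets <- as.integer(round(pmin(pmax(
    stats::rnorm(n_indel, 0, offset_sd_bp), -50), 50)))

  events <- tibble(
    sample_id = sample_id, class = classes, size = sizes, offset = offsets,
    read_count = 1L
  )
  if (nrow(events) > 0) {
    events <- events %>%
      group_by(.data$sample_id, .data$class, .data$size, .data$offset) %>%
      summarise(read_count = sum(.data$read_count), .groups = "drop")
  }
  bind_rows(
    tibble(sample_id = sample_id, class = "unmodified", size = 0L,
           offset = 0L, read_count = n_unmod),
    events
  )
}
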