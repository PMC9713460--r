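# Outcome summaries of simulated release scenarios.

#' Per-replicate outcome metrics of a simulated release
#'
#' First-passage summaries are computed on adult counts and reported in days
#' post-release (simulation day minus release day; first-passage conditions
#' are evaluated from the release day onward). An event that never
#' occurs within the simulated horizon is reported as `NA` (absent), never
#' as 0. Elimination thresholds are "fewer than one individual/allele" so
#' that the definitions carry over to the real-valued deterministic mode.
#'
#' * `day_ww_eliminated`: first day with fewer than one homozygous wild-type
#'   adult (both sexes combined);
#' * `peak_coverage` / `day_of_peak`: maximum drive-carrier coverage among
#'   adult females and the first day it is attained;
#' * `day_coverage_below_half`: first day after the peak with coverage below
#'   0.5 (the closing of the protection window);
#' * `day_h_eliminated`: first day with fewer than one drive allele anywhere
#'   in the population (adults, aquatic stages, and sperm stored by mated
#'   females);
#' * `final_freq_w/h/r`: allele frequencies among adults on the last day.
#'
#' @param sim A `gd_sim` object.
#' @return A tibble with one row per replicate.
#' @export
summary_metrics <- function(sim) {
  nW <- allele_dosage("W"); nH <- allele_dosage("H"); nR <- allele_dosage("R")
  ww_idx <- match("WW", sim$genotypes)
  rel_day <- sim$release_day
  cov_tbl <- effector_coverage(sim)

  from <- max(rel_day, 1L)
  purrr::imap_dfr(sim$reps, function(r, rep_i) {
    adults_ww <- r$f[, ww_idx] + r$m[, ww_idx]
    d_ww <- first_day(adults_ww < 1, from)
    cov <- cov_tbl$coverage[cov_tbl$rep == rep_i]
    peak <- max(cov)
    d_peak <- which.max(cov)
    after_peak <- seq_along(cov) > d_peak & cov < 0.5
    d_half <- first_day(after_peak)
    d_h <- first_day(r$h < 1, from)
    adults <- r$f[sim$days, ] + r$m[sim$days, ]
    tot_alleles <- 2 * sum(adults)
    tibble(
      rep = rep_i,
      day_ww_eliminated = pr_day(d_ww, rel_day),
      peak_coverage = peak,
      day_of_peak = pr_day(d_peak, rel_day),
      day_coverage_below_half = pr_day(d_half, rel_day),
      day_h_eliminated = pr_day(d_h, rel_day),
      final_freq_w = sum(adults * nW) / tot_alleles,
      final_freq_h = sum(adults * nH) / tot_alleles,
      final_freq_r = sum(adults * nR) / tot_alleles
    )
  })
}

first_day <- function(cond, from = 1L) {
  i <- which(cond & seq_along(cond) >= from)
  if (length(i) == 0) NA_integer_ else i[1]
}

pr_day <- function(day, release_day) {
  if (is.na(day)) NA_integer_ else as.integer(day - release_day)
}

#' Across-replicate summary of a simulated release
#'
#' Medians (and quartiles of the event days) of the per-replicate metrics
#' from [summary_metrics()]. `NA` event days (event never observed in that
#' replicate) are excluded from the day quantiles but counted in
#' `n_h_eliminated` / `n_ww_eliminated`.
#'
#' @param x A `gd_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance gd_sim
#' @export
glance.gd_sim <- function(x, ...) {
  m <- summary_metrics(x)
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_, NA_real_)
    else quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  }
  ww <- qs(m$day_ww_eliminated); hh <- qs(m$day_h_eliminated)
  tibble(
    n_reps = nrow(m),
    peak_coverage_median = median(m$peak_coverage),
    day_of_peak_median = median(m$day_of_peak),
    n_ww_eliminated = sum(!is.na(m$day_ww_eliminated)),
    day_ww_eliminated_median = ww[2],
    n_h_eliminated = sum(!is.na(m$day_h_eliminated)),
    day_h_eliminated_q1 = hh[1],
    day_h_eliminated_median = hh[2],
    day_h_eliminated_q3 = hh[3],
    final_freq_h_median = median(m$final_freq_h),
    final_freq_r_median = median(m$final_freq_r)
  )
}

#' Substitute parameters into a scenario configuration
#'
#' Deep-copies a base configuration (drive parameters plus lifecycle
#' parameters) and replaces the listed fields, recording the provenance of
#' each override. Useful for what-if runs that swap, e.g., the deposition
#' rate or the pupation-success modifiers of one line into another line's
#' configuration.
#'
#' @param base A list with elements `params` ([drive_params()]) and
#'   `lifecycle` ([lifecycle_params()]).
#' @param overrides Named list of replacement values; names must be fields
#'   of either component.
#' @return A configuration list like `base`, with an `"overrides"` attribute
#'   logging each substitution (`field`, `old`, `new`).
#' @export
#' @examples
#' base <- list(params = drive_params(dF = 0.19),
#'              lifecycle = lifecycle_params())
#' scenario_substitute(base, list(dF = 0.14, xiF = 1, xiM = 1))
scenario_substitute <- function(base, overrides = list()) {
  if (!all(c("params", "lifecycle") %in% names(base))) {
    abort("scenario_substitute: base must have `params` and `lifecycle`")
  }
  p <- unclass(base$params)
  lcp <- unclass(base$lifecycle)
  log <- tibble(field = character(), old = numeric(), new = numeric())
  for (nm in names(overrides)) {
    if (nm %in% names(p)) {
      log <- bind_rows(log, tibble(field = nm, old = p[[nm]],
                                   new = overrides[[nm]]))
      p[[nm]] <- overrides[[nm]]
    } else if (nm %in% names(lcp)) {
      log <- bind_rows(log, tibble(field = nm, old = lcp[[nm]],
                                   new = overrides[[nm]]))
      lcp[[nm]] <- overrides[[nm]]
    } else {
      abort(paste0("scenario_substitute: unknown parameter `", nm, "`"))
    }
  }
  out <- list(
    params = do.call(drive_params, p),
    lifecycle = do.call(lifecycle_params, lcp)
  )
  attr(out, "overrides") <- log
  out
}
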