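# Family-level cross analysis: inheritance rates, scoring filters, and
# deviation from Mendelian expectation.

#' Per-family marker-inheritance rates with a minimum-count filter
#'
#' Families with fewer than `min_n` scored offspring are excluded before any
#' summary is computed (the scoring rule used for box-plot figures); the
#' exclusions are reported via a message and kept in the `"excluded"`
#' attribute.
#'
#' @param records A data frame with one row per family: columns
#'   `n_offspring`, `n_marker_positive`, plus any grouping columns (e.g.
#'   `line`, `parent_sex`, `pool_label`).
#' @param min_n Minimum offspring per family for the family to be scored.
#' @return A tibble of retained families with an added `rate` column.
#' @export
#' @examples
#' fams <- tibble::tibble(line = "gd", n_offspring = c(26, 19, 40),
#'                        n_marker_positive = c(14, 10, 20))
#' inheritance_rates(fams)  # the 19-offspring family is dropped
inheritance_rates <- function(records, min_n = 20) {
  records <- as_tibble(records)
  need <- c("n_offspring", "n_marker_positive")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "inheritance_rates: missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(records) == 0) abort("inheritance_rates: no records")
  if (any(records$n_marker_positive > records$n_offspring)) {
    abort("inheritance_rates: n_marker_positive exceeds n_offspring")
  }
  keep <- records$n_offspring >= min_n
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) {
    inform(paste0(
      "inheritance_rates: excluded ", nrow(excluded), " famil",
      if (nrow(excluded) == 1) "y" else "ies",
      " with fewer than ", min_n, " offspring"
    ))
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("inheritance_rates: all families fell below the minimum count")
  }
  out$rate <- out$n_marker_positive / out$n_offspring
  attr(out, "excluded") <- excluded
  out
}

#' Group summaries of family rates (median and quartiles)
#'
#' Median and quartiles use the linear-interpolation quantile convention
#' (`stats::quantile` type 7), the convention common box-plot code assumes.
#'
#' @param rates A tibble from [inheritance_rates()] (must contain `rate`).
#' @param ... Grouping columns (tidy-select), e.g. `line, parent_sex`.
#' @return A tibble with `n_families`, `median_rate`, `q1`, `q3`, `min`,
#'   `max` per group.
#' @export
group_summary <- function(rates, ...) {
  rates <- as_tibble(rates)
  if (!("rate" %in% names(rates))) {
    abort("group_summary: `rates` must contain a `rate` column")
  }
  if (nrow(rates) == 0) {
    warn("group_summary: no retained families; returning empty summary")
    return(tibble(
      n_families = integer(), median_rate = numeric(), q1 = numeric(),
      q3 = numeric(), min = numeric(), max = numeric()
    ))
  }
  rates %>%
    group_by(...) %>%
    summarise(
      n_families = dplyr::n(),
      median_rate = median(.data$rate),
      q1 = quantile(.data$rate, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$rate, 0.75, type = 7, names = FALSE),
      min = min(.data$rate),
      max = max(.data$rate),
      .groups = "drop"
    )
}

#' Chi-square test against 1:1 Mendelian marker inheritance
#'
#' One-degree-of-freedom goodness-of-fit test of the observed
#' marker-positive/negative split against the 50:50 expectation of a
#' hemizygote x wild-type cross. Vectorised over families.
#'
#' @param n_positive Marker-positive offspring count(s).
#' @param n_total Total scored offspring count(s).
#' @return A tibble with `chi2` and `p`.
#' @export
#' @examples
#' mendelian_chisq(90, 100)  # chi2 = 64
mendelian_chisq <- function(n_positive, n_total) {
  if (any(n_total <= 0)) abort("mendelian_chisq: n_total must be positive")
  if (any(n_positive > n_total) || any(n_positive < 0)) {
    abort("mendelian_chisq: n_positive must be in [0, n_total]")
  }
  expected <- n_total / 2
  chi2 <- (n_positive - expected)^2 / expected +
    ((n_total - n_positive) - expected)^2 / expected
  tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-class activity rates of a trans-heterozygous assay
#'
#' Averages per-replicate activity fractions within each marker class and
#' locus, reporting mean and standard error of the mean (SEM = sd /
#' sqrt(replicates)). Replicates with zero larvae are excluded with a
#' warning.
#'
#' @param assay A data frame with one row per replicate x class: columns
#'   `marker_class`, `n_larvae`, and one or more `n_active_*` count columns
#'   (one per assayed locus).
#' @return A tibble with `marker_class`, `locus`, `n_replicates`, `mean`,
#'   `sem`.
#' @export
activity_rates <- function(assay) {
  assay <- as_tibble(assay)
  need <- c("marker_class", "n_larvae")
  missing_cols <- setdiff(need, names(assay))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "activity_rates: missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  activity_cols <- grep("^n_active", names(assay), value = TRUE)
  if (length(activity_cols) == 0) {
    abort("activity_rates: no `n_active_*` columns found")
  }
  if (any(assay$n_larvae == 0)) {
    warn("activity_rates: excluding replicate(s) with zero larvae")
    assay <- assay[assay$n_larvae > 0, , drop = FALSE]
  }
  assay %>%
    tidyr::pivot_longer(
      dplyr::all_of(activity_cols),
      names_to = "locus", names_prefix = "n_active_", values_to = "n_active"
    ) %>%
    mutate(fraction = .data$n_active / .data$n_larvae) %>%
    group_by(.data$marker_class, .data$locus) %>%
    summarise(
      n_replicates = dplyr::n(),
      mean = mean(.data$fraction),
      sem = if (dplyr::n() > 1) sd(.data$fraction) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
}

#' Nonparametric group comparison of family rates
#'
#' Thin wrapper delegating to `stats::kruskal.test` with
#' `stats::pairwise.wilcox.test` (Bonferroni-adjusted) as the post hoc;
#' exposed for convenience, not re-derived. Note the post hoc is pairwise
#' Wilcoxon rather than Dunn's test.
#'
#' @param rates Tibble containing `rate` and the grouping column.
#' @param group Name of the grouping column (string).
#' @return A list with elements `kruskal` (htest) and `pairwise`
#'   (pairwise.htest), or `NULL` pairwise when fewer than 3 groups.
#' @export
compare_groups <- function(rates, group) {
  rates <- as_tibble(rates)
  g <- factor(rates[[group]])
  kw <- stats::kruskal.test(rates$rate, g)
  pw <- if (nlevels(g) >= 2) {
    suppressWarnings(
      stats::pairwise.wilcox.test(rates$rate, g, p.adjust.method = "bonferroni")
    )
  }
  list(kruskal = kw, pairwise = pw)
}
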