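# Amplicon-sequencing indel summaries: per-read edit classifications are
# consumed (CRISPResso-style), never called from raw reads.

amplicon_classes <- c("unmodified", "insertion", "deletion", "substitution")

#' Read and write per-read amplicon edit classifications
#'
#' The minimal exchange dialect is a TSV with columns `sample_id`, `class`
#' (`unmodified`, `insertion`, `deletion`, `substitution`), `size` (bp; 0
#' for unmodified), `offset` (signed bp from the predicted cut site; 0 for
#' unmodified) and `read_count`. This corresponds to a flattened per-allele
#' summary of a CRISPResso-style quantification: one row per distinct edit
#' (or the unmodified allele) per sample, with `read_count` reads supporting
#' it.
#'
#' @param path File path.
#' @param x A classification tibble.
#' @return `read_amplicon_classes()` returns a tibble;
#'   `write_amplicon_classes()` returns `path` invisibly.
#' @export
read_amplicon_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "size", "offset", "read_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "amplicon TSV ", path, ": missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(df$class), amplicon_classes)
  if (length(bad) > 0) {
    abort(paste0("amplicon TSV ", path, ": unknown class(es): ",
                 paste(bad, collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_amplicon_classes
#' @export
write_amplicon_classes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Proportion of amplicon reads containing an indel
#'
#' Insertions, deletions and substitutions are summed into a single "indel"
#' class (substitutions at the cut site are treated as composite
#' deletion/insertion events); the proportion is that sum over all reads.
#' Set `include_substitutions = FALSE` for a sensitivity analysis that
#' drops the substitution class from both numerator and denominator
#' interpretation (they still count as reads).
#'
#' @param counts Classification tibble (see [read_amplicon_classes()]).
#' @param include_substitutions Count substitutions as indels (default TRUE).
#' @return A tibble with `sample_id`, `n_reads`, `n_indel`, `proportion`.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   sample_id = "s1",
#'   class = c("unmodified", "insertion", "deletion", "substitution"),
#'   size = c(0, 3, 12, 1), offset = c(0, 0, -2, 1),
#'   read_count = c(65, 10, 20, 5)
#' )
#' indel_proportion(x)  # 0.35
indel_proportion <- function(counts, include_substitutions = TRUE) {
  counts <- as_tibble(counts)
  indel_classes <- c("insertion", "deletion",
                     if (include_substitutions) "substitution")
  counts %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_reads = sum(.data$read_count),
      n_indel = sum(.data$read_count[.data$class %in% indel_classes]),
      .groups = "drop"
    ) %>%
    mutate(proportion = {
      if (any(.data$n_reads == 0)) abort("indel_proportion: sample with zero reads")
      .data$n_indel / .data$n_reads
    })
}

#' Flag indel proportions exceeding the hemizygous ceiling
#'
#' In pools of outcrossed, drive-negative larvae every individual carries at
#' most one edited allele, so at most 50% of amplicons can contain an indel.
#' Proportions above the threshold indicate an artifact -- typically PCR
#' chimera formation during pooled amplification -- that overestimates GDBI
#' abundance.
#'
#' @param proportion Numeric vector of indel proportions in `[0, 1]`.
#' @param threshold Theoretical ceiling (default 0.5; exposed because pool
#'   composition can shift it).
#' @return A tibble with `proportion`, `flagged`, `note`.
#' @export
#' @examples
#' chimera_flag(c(0.145, 0.64))
chimera_flag <- function(proportion, threshold = 0.5) {
  if (any(proportion < 0 | proportion > 1)) {
    abort("chimera_flag: proportion must be in [0, 1]")
  }
  flagged <- proportion > threshold
  tibble(
    proportion = proportion,
    flagged = flagged,
    note = ifelse(
      flagged,
      paste0("exceeds the ", format(threshold * 100),
             "% hemizygous ceiling; possible PCR chimera artifact"),
      NA_character_
    )
  )
}

#' Indel size and position spectrum
#'
#' Histograms event sizes per class and reports the fraction of events whose
#' cut-site offset lies within `window_bp`, together with the largest
#' deletion and insertion. Events are weighted by their supporting read
#' counts.
#'
#' @param counts Classification tibble with per-event rows (`size`,
#'   `offset` populated for edited classes).
#' @param window_bp Window half-width around the cut site (default 50 bp).
#' @return A list with `histogram` (tibble: `class`, `size`, `n_reads`),
#'   `fraction_within_window`, `max_deletion_bp`, `max_insertion_bp`.
#' @export
size_spectrum <- function(counts, window_bp = 50) {
  counts <- as_tibble(counts)
  events <- counts[counts$class != "unmodified" & counts$read_count > 0, ,
                   drop = FALSE]
  if (nrow(events) == 0) {
    abort("size_spectrum: no edit events present (proportions are still computable)")
  }
  if (any(events$size <= 0)) abort("size_spectrum: event sizes must be positive")
  hist <- events %>%
    group_by(.data$class, .data$size) %>%
    summarise(n_reads = sum(.data$read_count), .groups = "drop") %>%
    arrange(.data$class, .data$size)
  within <- sum(events$read_count[abs(events$offset) <= window_bp]) /
    sum(events$read_count)
  dels <- events$size[events$class == "deletion"]
  ins <- events$size[events$class == "insertion"]
  list(
    histogram = hist,
    fraction_within_window = within,
    max_deletion_bp = if (length(dels)) max(dels) else NA_integer_,
    max_insertion_bp = if (length(ins)) max(ins) else NA_integer_
  )
}
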