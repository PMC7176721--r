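#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom (upper tail), `k` the number of available p-values.
#' Missing comparisons are omitted by the caller, never zero-filled.
#'
#' @param p Numeric vector of 1 to 6 p-values in (0, 1].
#' @return The merged p-value, or `NA_real_` for an empty input.
#' @export
fisher_merge <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  if (any(p <= 0)) stop("Fisher's method requires p > 0")
  stopifnot(all(p <= 1))
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Maximum available log2 fold change
#'
#' Signed maximum over the comparisons in which a fold change was measured.
#'
#' @param log2fc Numeric vector, `NA` for unavailable comparisons.
#' @return The maximum, or `NA_real_` when none is defined.
#' @export
max_log2fc <- function(log2fc) {
  log2fc <- log2fc[!is.na(log2fc)]
  if (length(log2fc) == 0) return(NA_real_)
  max(log2fc)
}

#' Compose the enriched protein set and merged volcano
#'
#' A protein enters the enriched set if (a) it is significantly enriched
#' toward MBR+ (`significant_enriched`) in at least one of the six comparisons
#' (reason tag `DIFFERENTIAL:<comparison>`), or (b) it is quantitatively
#' present in MBR+ but absent in at least `config$absent_rule_min_controls`
#' distinct control fractions (reason tags `ABSENT_IN:<comparison>`; a protein
#' absent versus the same fraction in both preparations counts that fraction
#' once). Each protein also receives its merged-volcano coordinates: the
#' maximum log2 fold change over the available comparisons and the
#' Fisher-merged p-value over the available raw p-values — both computed only
#' when data are available.
#'
#' @param results An `lfq_results` object from [run_all_comparisons()] (or a
#'   named list of `lfq_comparison` tibbles).
#' @param config An [analysis_config()].
#' @return A tibble of class `lfq_merged`, one row per protein:
#'   `protein_id`, `max_log2fc`, `merged_p`, `n_comparisons_available`,
#'   `n_significant_fractions` (distinct control fractions with a significant
#'   enriched comparison; the volcano color classes), `enriched`, `reasons`
#'   (list-column of tags, empty when not enriched).
#' @export
compose_enriched_set <- function(results, config = analysis_config()) {
  comparisons <- if (inherits(results, "lfq_results")) results$comparisons else results
  if (length(comparisons) == 0) stop("no comparison results supplied")
  long <- purrr::imap_dfr(comparisons, function(res, cid) {
    meta <- attr(res, "meta")
    dplyr::mutate(tibble::as_tibble(unclass(res)),
                  comparison_id = cid,
                  control_fraction = meta$control_fraction)
  })

  merged <- long |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      max_log2fc = max_log2fc(.data$log2fc),
      merged_p = fisher_merge(.data$p),
      n_comparisons_available = sum(.data$status != "DISCARDED"),
      n_significant_fractions = dplyr::n_distinct(
        .data$control_fraction[.data$significant_enriched]
      ),
      n_absent_fractions = dplyr::n_distinct(
        .data$control_fraction[.data$status == "PRESENT_ABSENT_PLUS"]
      ),
      diff_tags = list(paste0("DIFFERENTIAL:",
                              .data$comparison_id[.data$significant_enriched],
                              recycle0 = TRUE)),
      absent_tags = list(paste0("ABSENT_IN:",
                                .data$comparison_id[.data$status == "PRESENT_ABSENT_PLUS"],
                                recycle0 = TRUE)),
      .groups = "drop"
    )

  merged <- merged |>
    dplyr::mutate(
      reasons = purrr::pmap(
        list(.data$diff_tags, .data$absent_tags, .data$n_absent_fractions),
        function(d, a, na) c(d, if (na >= config$absent_rule_min_controls) a else character(0))
      ),
      enriched = lengths(.data$reasons) > 0
    ) |>
    dplyr::select(-"diff_tags", -"absent_tags", -"n_absent_fractions") |>
    dplyr::arrange(.data$protein_id)
  class(merged) <- c("lfq_merged", class(merged))
  merged
}

#' Named significant sets per comparison
#'
#' @param results An `lfq_results` object or named list of `lfq_comparison`
#'   tibbles.
#' @return A named list of protein-id character vectors (proteins flagged
#'   `significant` in each comparison), ready for [upset_counts()].
#' @export
significant_sets <- function(results) {
  comparisons <- if (inherits(results, "lfq_results")) results$comparisons else results
  lapply(comparisons, function(res) res$protein_id[res$significant])
}

#' Exclusive intersection counts (UpSet semantics)
#'
#' For every non-empty combination of the input sets, the number of elements
#' belonging to exactly that combination. Counts sum to the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return A tibble with `combination` (set names joined by `"&"`), `degree`
#'   and `count`, sorted by degree then combination.
#' @export
upset_counts <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  universe <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  combos <- tidyr::expand_grid(!!!stats::setNames(rep(list(c(FALSE, TRUE)), k), names(sets)))
  combos <- combos[rowSums(as.matrix(combos)) > 0, , drop = FALSE]
  pattern_of <- function(mat) apply(mat, 1, function(z) paste(as.integer(z), collapse = ""))
  obs_pattern <- if (length(universe) > 0) pattern_of(membership) else character(0)
  combo_mat <- as.matrix(combos)
  tibble::tibble(
    combination = apply(combo_mat, 1, function(z) paste(names(sets)[z], collapse = "&")),
    degree = rowSums(combo_mat),
    count = vapply(pattern_of(combo_mat), function(pt) sum(obs_pattern == pt),
                   integer(1), USE.NAMES = FALSE)
  ) |>
    dplyr::arrange(.data$degree, .data$combination)
}

#' Overlap of an enriched set with an external protein list
#'
#' @param enriched Character vector of protein identifiers (after any
#'   identifier mapping).
#' @param external Non-empty character vector of identifiers.
#' @return A one-row tibble: `n_overlap` = size of the intersection,
#'   `fraction_of_external` = intersection / |external|.
#' @export
overlap_with_list <- function(enriched, external) {
  external <- unique(external)
  if (length(external) == 0) stop("external list is empty")
  inter <- length(intersect(unique(enriched), external))
  tibble::tibble(
    n_overlap = inter,
    fraction_of_external = inter / length(external)
  )
}
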