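#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` proteins from a
#' background of `N` of which `K` belong to the cluster. Exact at small sizes.
#'
#' @param k Observed cluster members in the target list.
#' @param K Cluster members in the background.
#' @param n Target list size.
#' @param N Background size.
#' @return The over-representation p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(
    length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1,
    k >= 0, K >= 0, n >= 0, N >= 0,
    K <= N, n <= N, k <= min(n, K),
    k >= max(0, n + K - N)
  )
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation of functional clusters in a target protein list
#'
#' One hypergeometric test per cluster label, against the full MS-identified
#' background. Proteins annotated to several clusters count in each of them;
#' unannotated proteins contribute to the background and target sizes but to
#' no cluster.
#'
#' @param target Character vector of protein ids, a subset of `background`.
#' @param background Character vector of protein ids (the identified set).
#' @param annotation Data frame with columns `protein_id` and `cluster`
#'   (multi-label allowed; see [read_cluster_annotation()]).
#' @param p_display_cutoff Reporting threshold carried into the output
#'   (`displayed = p <= cutoff`); not a multiplicity adjustment (default 0.1).
#' @return A tibble of class `lfq_cluster_result` with one row per cluster:
#'   `cluster`, `k`, `K`, `n`, `N`, `p`, `displayed`, sorted by `p`.
#' @export
test_clusters <- function(target, background, annotation, p_display_cutoff = 0.1) {
  target <- unique(target)
  background <- unique(background)
  extra <- setdiff(target, background)
  if (length(extra) > 0) {
    stop("target proteins missing from the background: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) sprintf(" (and %d more)", length(extra) - 5) else "")
  }
  annotation <- dplyr::distinct(tibble::as_tibble(annotation)[, c("protein_id", "cluster")])
  annotation <- annotation[annotation$protein_id %in% background, , drop = FALSE]
  if (nrow(annotation) == 0) {
    warning("no annotated proteins in the background; empty result")
    return(tibble::tibble(cluster = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = double(),
                          displayed = logical()))
  }
  n_target <- length(target)
  n_background <- length(background)
  res <- annotation |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$protein_id),
      k = dplyr::n_distinct(intersect(.data$protein_id, target)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n_target, N = n_background,
      p = purrr::map2_dbl(.data$k, .data$K,
                          ~ hypergeom_upper_tail(.x, .y, n_target, n_background)),
      displayed = .data$p <= p_display_cutoff
    ) |>
    dplyr::select("cluster", "k", "K", "n", "N", "p", "displayed") |>
    dplyr::arrange(.data$p, .data$cluster)
  class(res) <- c("lfq_cluster_result", class(res))
  res
}
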