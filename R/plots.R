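#' Merged volcano plot
#'
#' Maximum log2 fold change (MBR+ vs the control fractions) against the
#' -log10 Fisher-merged p-value, colored by the number of distinct control
#' fractions in which the protein was significantly enriched.
#'
#' @param merged An `lfq_merged` tibble from [compose_enriched_set()].
#' @param fdr_level Reference line level (default 0.05).
#' @param fc_threshold_raw Reference fold-change gate (default 1.3).
#' @return A ggplot object.
#' @export
plot_merged_volcano <- function(merged, fdr_level = 0.05, fc_threshold_raw = 1.3) {
  d <- dplyr::filter(merged, !is.na(.data$max_log2fc), !is.na(.data$merged_p))
  d$class <- factor(pmin(d$n_significant_fractions, 3),
                    levels = 0:3,
                    labels = c("none", "1 fraction", "2 fractions", "3 fractions"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$max_log2fc,
                                  y = -log10(.data$merged_p),
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold_raw),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(fdr_level),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(none = "grey70", `1 fraction` = "forestgreen",
                 `2 fractions` = "royalblue", `3 fractions` = "firebrick"),
      name = "significant vs"
    ) +
    ggplot2::labs(x = "max log2 fold change (MBR+ / control)",
                  y = "-log10 merged p") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lfq_merged <- function(object, ...) plot_merged_volcano(object, ...)

#' Bar chart of exclusive intersection counts
#'
#' @param counts Tibble from [upset_counts()].
#' @param drop_empty Drop zero-count combinations (default TRUE).
#' @return A ggplot object.
#' @export
plot_upset_counts <- function(counts, drop_empty = TRUE) {
  d <- if (drop_empty) dplyr::filter(counts, .data$count > 0) else counts
  d$combination <- stats::reorder(d$combination, -d$count)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combination, y = .data$count)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = NULL, y = "proteins in exactly this combination") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cluster over-representation bar chart
#'
#' Cluster sizes in the target list with a -log10 p color gradient; clusters
#' above the display cutoff are drawn in grey.
#'
#' @param clusters An `lfq_cluster_result` tibble from [test_clusters()].
#' @return A ggplot object.
#' @export
plot_cluster_enrichment <- function(clusters) {
  d <- dplyr::mutate(clusters,
                     neglog10p = -log10(.data$p),
                     cluster = stats::reorder(.data$cluster, .data$k))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$cluster,
                                  fill = .data$neglog10p)) +
    ggplot2::geom_col(data = dplyr::filter(d, !.data$displayed), fill = "grey75") +
    ggplot2::geom_col(data = dplyr::filter(d, .data$displayed)) +
    ggplot2::scale_fill_gradient(low = "mistyrose", high = "firebrick",
                                 name = "-log10 p") +
    ggplot2::labs(x = "proteins in cluster (target list)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lfq_cluster_result <- function(object, ...) plot_cluster_enrichment(object, ...)
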