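#' Run every MBR+ vs control comparison in a design
#'
#' Derives the comparison grid from the design (each control fraction crossed
#' with each preparation method that has MBR+ samples — the study design
#' yields six comparisons), partitions each into tested / present-absent
#' classes, imputes the tested block and runs the moderated-t analysis.
#'
#' @param x A filtered, log2-transformed, median-centered `lfq_tbl`.
#' @param config An [analysis_config()].
#' @return An object of class `lfq_results`: `comparisons` (named list of
#'   `lfq_comparison` tibbles) and `manifest` (per-step counts; see
#'   [run_pipeline()]).
#' @export
run_all_comparisons <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "lfq_tbl"))
  if (x$scale != "log2") stop("run_all_comparisons expects a log2-scale table")
  grid <- x$design |>
    dplyr::filter(.data$fraction != "MBR_plus") |>
    dplyr::distinct(.data$fraction, .data$prep)
  has_plus <- unique(x$design$prep[x$design$fraction == "MBR_plus"])
  grid <- grid[grid$prep %in% has_plus, , drop = FALSE]
  if (nrow(grid) == 0) stop("design contains no MBR_plus vs control comparison")

  comparisons <- list()
  counts <- list()
  for (i in seq_len(nrow(grid))) {
    frame <- partition_presence_absence(x, grid$fraction[i], grid$prep[i], config)
    res <- run_comparison(frame, config)
    comparisons[[frame$comparison_id]] <- res
    counts[[frame$comparison_id]] <- table(factor(
      res$status,
      levels = c("TESTED", "FC_FILTERED", "PRESENT_ABSENT_PLUS",
                 "PRESENT_ABSENT_CONTROL", "DISCARDED")
    ))
  }
  structure(
    list(
      comparisons = comparisons,
      manifest = list(n_proteins = nrow(x$values), status_counts = counts)
    ),
    class = "lfq_results"
  )
}

#' @export
print.lfq_results <- function(x, ...) {
  cat(sprintf("<lfq_results> %d comparisons over %d proteins\n",
              length(x$comparisons), x$manifest$n_proteins))
  print(purrr::map_dfr(x$comparisons, glance))
  invisible(x)
}

#' @export
glance.lfq_results <- function(x, ...) {
  purrr::map_dfr(x$comparisons, glance)
}

#' Run the full enrichment pipeline
#'
#' Orchestrates reading (or simulation), identification and quantification
#' filters, log2 transform, within-condition median centering, the six
#' comparisons, enriched-set composition and (optionally) cluster
#' over-representation; writes the result tables when `out_dir` is given.
#' Identical inputs and config produce byte-identical outputs.
#'
#' @param config An [analysis_config()], or the path to a YAML file whose
#'   keys mirror [analysis_config()] plus `protein_groups`, `design` and
#'   optionally `cluster_annotation` file paths.
#' @param table An `lfq_tbl` at raw scale (alternative to file paths in the
#'   config).
#' @param cluster_annotation Optional annotation tibble (`protein_id`,
#'   `cluster`).
#' @param out_dir Optional output directory for [write_results()].
#' @return A list of class `lfq_run`: `results` (`lfq_results`), `merged`
#'   (`lfq_merged`), `clusters` (or `NULL`), and `manifest` — config digest,
#'   seed, per-step row counts and per-comparison status counts.
#' @export
run_pipeline <- function(config = analysis_config(), table = NULL,
                         cluster_annotation = NULL, out_dir = NULL) {
  if (is.character(config)) {
    cfg_file <- yaml::read_yaml(config)
    paths <- cfg_file[c("protein_groups", "design", "cluster_annotation")]
    cfg_args <- cfg_file[setdiff(names(cfg_file),
                                 c("protein_groups", "design", "cluster_annotation", "out_dir"))]
    config <- do.call(analysis_config, cfg_args)
    if (is.null(table)) {
      if (is.null(paths$protein_groups) || is.null(paths$design)) {
        stop("config file must name 'protein_groups' and 'design' inputs")
      }
      table <- read_protein_groups(paths$protein_groups, read_design(paths$design))
    }
    if (is.null(cluster_annotation) && !is.null(paths$cluster_annotation)) {
      cluster_annotation <- read_cluster_annotation(paths$cluster_annotation)
    }
    if (is.null(out_dir)) out_dir <- cfg_file$out_dir
  }
  stopifnot(inherits(config, "lfq_config"), inherits(table, "lfq_tbl"))

  n_input <- nrow(table$values)
  flagged <- filter_identifications(table, config)
  n_after_flags <- nrow(flagged$values)
  quantified <- filter_min_quantified(flagged, config)
  n_after_quant <- nrow(quantified$values)
  normalized <- median_center(log2_transform(quantified))
  results <- run_all_comparisons(normalized, config)
  merged <- compose_enriched_set(results, config)

  clusters <- NULL
  if (!is.null(cluster_annotation)) {
    clusters <- test_clusters(
      target = merged$protein_id[merged$enriched],
      background = quantified$records$protein_id,
      annotation = cluster_annotation
    )
  }
  manifest <- list(
    config_digest = rlang::hash(unclass(config)),
    seed = config$seed,
    n_input = n_input,
    n_after_identification_filter = n_after_flags,
    n_after_quantified_filter = n_after_quant,
    removed = as.list(attr(flagged, "removed")),
    status_counts = lapply(results$manifest$status_counts, as.list),
    n_enriched = sum(merged$enriched),
    version = as.character(utils::packageVersion("lfqenrich"))
  )
  if (!is.null(out_dir)) {
    write_results(results, merged, out_dir, config, clusters)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(
    list(results = results, merged = merged, clusters = clusters,
         manifest = manifest),
    class = "lfq_run"
  )
}

#' @export
print.lfq_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<lfq_run> %d proteins -> %d after identification filter -> %d quantified; %d enriched\n",
    m$n_input, m$n_after_identification_filter, m$n_after_quantified_filter, m$n_enriched
  ))
  invisible(x)
}
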