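#' Read a sample-design table
#'
#' @param path Tab-separated file with columns `sample_id`, `fraction`,
#'   `prep`, `replicate`.
#' @return A design tibble suitable for [lfq_table()] / [read_protein_groups()].
#' @export
read_design <- function(path) {
  des <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    fraction = readr::col_character(),
    prep = readr::col_character(),
    replicate = readr::col_integer()
  ))
  need <- c("sample_id", "fraction", "prep", "replicate")
  missing <- setdiff(need, names(des))
  if (length(missing) > 0) {
    stop("design table is missing column(s): ", paste(missing, collapse = ", "))
  }
  des
}

#' Read a MaxQuant-style protein-groups table
#'
#' Parses the tab-separated protein-groups output dialect: one row per protein
#' group, `"LFQ intensity <sample_id>"` columns, `"+"`-flagged columns for
#' reverse hits, potential contaminants and proteins only identified by site,
#' and a unique-peptide count. Intensities of 0 (or empty) encode
#' non-detection and are recorded as missing; no row is dropped at parse time
#' — all filtering is explicit and downstream ([filter_identifications()]).
#'
#' @param path Path to the tab-separated protein-groups file.
#' @param design Design data frame (see [read_design()]); every `sample_id`
#'   must match an `"LFQ intensity <sample_id>"` column.
#' @return An [lfq_table()] at raw scale, row order preserved.
#' @export
read_protein_groups <- function(path, design) {
  design <- tibble::as_tibble(design)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  lfq_cols <- paste("LFQ intensity", design$sample_id)
  missing_cols <- lfq_cols[!lfq_cols %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("design sample(s) without an LFQ intensity column: ",
         paste(sub("^LFQ intensity ", "", missing_cols), collapse = ", "))
  }
  if (!"Majority protein IDs" %in% names(raw)) {
    stop("protein-groups table lacks a 'Majority protein IDs' column")
  }

  flag <- function(col) {
    if (col %in% names(raw)) !is.na(raw[[col]]) & raw[[col]] == "+" else rep(FALSE, nrow(raw))
  }
  # "Peptide counts (unique)" lists one count per protein in the group,
  # semicolon-separated; the leading count belongs to the majority protein.
  upep <- if ("Peptide counts (unique)" %in% names(raw)) {
    as.integer(sub(";.*$", "", raw[["Peptide counts (unique)"]]))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  records <- tibble::tibble(
    protein_id = raw[["Majority protein IDs"]],
    gene_name = if ("Gene names" %in% names(raw)) {
      dplyr::coalesce(raw[["Gene names"]], "")
    } else {
      ""
    },
    is_reverse = flag("Reverse"),
    is_contaminant = flag("Potential contaminant"),
    is_only_by_site = flag("Only identified by site"),
    unique_peptides = dplyr::coalesce(upep, 0L)
  )
  if (anyDuplicated(records$protein_id)) {
    dup <- unique(records$protein_id[duplicated(records$protein_id)])
    stop("duplicate protein_id in protein-groups table: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }

  values <- matrix(NA_real_, nrow(raw), nrow(design))
  for (j in seq_len(nrow(design))) {
    txt <- raw[[lfq_cols[j]]]
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(txt) & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric intensity at row %d, column '%s': '%s'",
                   bad[1], lfq_cols[j], txt[bad[1]]))
    }
    v[is.na(v) | v == 0] <- NA_real_
    values[, j] <- v
  }
  lfq_table(records, design, values, scale = "raw")
}

#' Write an LFQ table as a protein-groups + design file pair
#'
#' Emits the exact dialect [read_protein_groups()] consumes (missing raw
#' intensities written as 0), so simulated data can be fed back through the
#' reading path.
#'
#' @param x An `lfq_tbl` at raw scale.
#' @param pg_path,design_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_protein_groups <- function(x, pg_path, design_path) {
  stopifnot(inherits(x, "lfq_tbl"))
  if (x$scale != "raw") stop("write_protein_groups expects a raw-scale table")
  flag_col <- function(b) ifelse(b, "+", "")
  out <- tibble::tibble(
    `Majority protein IDs` = x$records$protein_id,
    `Gene names` = x$records$gene_name,
    Reverse = flag_col(x$records$is_reverse),
    `Potential contaminant` = flag_col(x$records$is_contaminant),
    `Only identified by site` = flag_col(x$records$is_only_by_site),
    `Peptide counts (unique)` = as.character(x$records$unique_peptides)
  )
  vals <- x$values
  vals[is.na(vals)] <- 0
  for (j in seq_len(ncol(vals))) {
    out[[paste("LFQ intensity", x$design$sample_id[j])]] <- vals[, j]
  }
  readr::write_tsv(out, pg_path)
  readr::write_tsv(x$design, design_path)
  invisible(c(pg_path, design_path))
}

#' Read a protein-to-cluster annotation table
#'
#' @param path Two-column tab-separated file (`protein_id`, `cluster`), no
#'   header required if the first row parses as data; a protein may appear on
#'   several rows (multi-label).
#' @return A tibble with columns `protein_id` and `cluster`, one row per
#'   distinct (protein, cluster) pair.
#' @export
read_cluster_annotation <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty cluster annotation file: ", path)
    return(tibble::tibble(protein_id = character(), cluster = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed cluster annotation at line %d: expected 2 tab-separated fields", bad[1]))
  }
  ann <- tibble::tibble(
    protein_id = vapply(parts, `[[`, "", 1),
    cluster = vapply(parts, `[[`, "", 2)
  )
  if (identical(ann$protein_id[1], "protein_id")) ann <- ann[-1, ]
  dplyr::distinct(ann)
}

#' Write the pipeline's result tables
#'
#' Writes tab-separated tables (per-comparison results, merged volcano,
#' enriched set with reasons, UpSet counts, and cluster enrichment when
#' supplied), each preceded by a run-metadata comment line carrying a config
#' digest and the seed. Re-running with identical inputs and config produces
#' byte-identical files.
#'
#' @param results An `lfq_results` object from [run_all_comparisons()].
#' @param merged Merged-record tibble from [compose_enriched_set()].
#' @param out_dir Output directory (created if needed).
#' @param config The [analysis_config()] used.
#' @param clusters Optional cluster-enrichment tibble from [test_clusters()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, merged, out_dir, config, clusters = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- sprintf("# lfqenrich config_digest=%s seed=%d", rlang::hash(unclass(config)),
                  config$seed)
  write_one <- function(tbl, file) {
    path <- file.path(out_dir, file)
    writeLines(meta, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
    path
  }
  paths <- character()
  for (cid in names(results$comparisons)) {
    paths <- c(paths, write_one(results$comparisons[[cid]],
                                paste0("comparison_", gsub("[^A-Za-z0-9_.-]", "_", cid), ".tsv")))
  }
  merged_out <- dplyr::mutate(
    merged,
    reasons = vapply(.data$reasons, paste, "", collapse = ";")
  )
  paths <- c(paths, write_one(merged_out, "merged_volcano.tsv"))
  paths <- c(paths, write_one(dplyr::filter(merged_out, .data$enriched), "enriched_set.tsv"))
  paths <- c(paths, write_one(upset_counts(significant_sets(results)), "upset_counts.tsv"))
  if (!is.null(clusters)) paths <- c(paths, write_one(clusters, "cluster_enrichment.tsv"))
  invisible(paths)
}
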