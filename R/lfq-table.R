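#' LFQ intensity table
#'
#' The central container of the package: a proteins x samples intensity matrix
#' together with per-protein identification metadata and the experimental
#' design that binds sample columns to condition (fraction x preparation
#' method) and replicate. Missing values (non-detections) are encoded as `NA`
#' in the matrix; every downstream operation treats `NA` cells as carrying no
#' information. The matrix is either on the raw intensity scale (`scale =
#' "raw"`) or, after [log2_transform()], on the log2 scale (`"log2"`); the
#' transition happens exactly once.
#'
#' @param records A data frame with one row per protein group and columns
#'   `protein_id` (non-empty, unique), `gene_name`, `is_reverse`,
#'   `is_contaminant`, `is_only_by_site` (logicals) and `unique_peptides`
#'   (non-negative integer).
#' @param design A data frame with one row per sample and columns `sample_id`,
#'   `fraction` (one of `"MBR_plus"`, `"MBR_minus"`, `"MBRE"`, `"Total"`),
#'   `prep` (`"gel"` or `"efasp"`) and `replicate` (positive integer);
#'   `(fraction, prep, replicate)` must be unique.
#' @param values Numeric matrix, proteins x samples, `NA` = not detected.
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An object of class `lfq_tbl`.
#' @export
lfq_table <- function(records, design, values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  records <- tibble::as_tibble(records)
  design <- tibble::as_tibble(design)
  values <- as.matrix(values)
  x <- structure(
    list(records = records, design = design, values = values, scale = scale),
    class = "lfq_tbl"
  )
  validate_lfq_table(x)
}

lfq_fractions <- c("MBR_plus", "MBR_minus", "MBRE", "Total")
lfq_preps <- c("gel", "efasp")

validate_lfq_table <- function(x) {
  rec <- x$records
  des <- x$design
  need_rec <- c("protein_id", "gene_name", "is_reverse", "is_contaminant",
                "is_only_by_site", "unique_peptides")
  missing_rec <- setdiff(need_rec, names(rec))
  if (length(missing_rec) > 0) {
    stop("records is missing column(s): ", paste(missing_rec, collapse = ", "))
  }
  if (anyNA(rec$protein_id) || any(!nzchar(rec$protein_id))) {
    stop("protein_id must be non-empty")
  }
  if (anyDuplicated(rec$protein_id)) {
    dup <- unique(rec$protein_id[duplicated(rec$protein_id)])
    stop("duplicate protein_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  need_des <- c("sample_id", "fraction", "prep", "replicate")
  missing_des <- setdiff(need_des, names(des))
  if (length(missing_des) > 0) {
    stop("design is missing column(s): ", paste(missing_des, collapse = ", "))
  }
  if (!all(des$fraction %in% lfq_fractions)) {
    stop("design fraction must be one of: ", paste(lfq_fractions, collapse = ", "))
  }
  if (!all(des$prep %in% lfq_preps)) {
    stop("design prep must be one of: ", paste(lfq_preps, collapse = ", "))
  }
  if (anyDuplicated(des[, c("fraction", "prep", "replicate")])) {
    stop("design (fraction, prep, replicate) must be unique")
  }
  if (anyDuplicated(des$sample_id)) stop("design sample_id must be unique")
  if (nrow(x$values) != nrow(rec) || ncol(x$values) != nrow(des)) {
    stop(sprintf(
      "values is %d x %d but records x design is %d x %d",
      nrow(x$values), ncol(x$values), nrow(rec), nrow(des)
    ))
  }
  rownames(x$values) <- rec$protein_id
  colnames(x$values) <- des$sample_id
  if (x$scale == "raw" && any(x$values <= 0, na.rm = TRUE)) {
    stop("raw-scale intensities must be positive (zeros encode missing and must be NA)")
  }
  x
}

#' @export
print.lfq_tbl <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(sprintf(
    "<lfq_tbl> %d proteins x %d samples [%s scale], %d missing cells (%.1f%%)\n",
    nrow(x$values), ncol(x$values), x$scale, n_missing,
    100 * n_missing / max(1, length(x$values))
  ))
  cond <- dplyr::count(x$design, .data$fraction, .data$prep)
  cat("conditions:",
      paste(sprintf("%s/%s (n=%d)", cond$fraction, cond$prep, cond$n), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.lfq_tbl <- function(x) dim(x$values)

#' Condition label of each design row
#'
#' A condition is the crossing of fraction and preparation method; gel and
#' eFASP samples are never analyzed together.
#'
#' @param design A design data frame (see [lfq_table()]).
#' @return Character vector, e.g. `"MBR_plus.gel"`.
#' @export
condition_id <- function(design) paste(design$fraction, design$prep, sep = ".")

#' Tidy an LFQ table into long format
#'
#' @param x An `lfq_tbl`.
#' @param ... Unused.
#' @return A tibble with one row per protein x sample: `protein_id`,
#'   `sample_id`, `fraction`, `prep`, `replicate`, `intensity` (NA when not
#'   detected) and `observed`.
#' @export
tidy.lfq_tbl <- function(x, ...) {
  long <- tibble::as_tibble(x$values)
  long$protein_id <- x$records$protein_id
  long <- tidyr::pivot_longer(long, -"protein_id",
                              names_to = "sample_id", values_to = "intensity")
  long <- dplyr::left_join(long, x$design, by = "sample_id")
  dplyr::mutate(long, observed = !is.na(.data$intensity))
}

#' One-line summary of an LFQ table
#'
#' @param x An `lfq_tbl`.
#' @param ... Unused.
#' @return A one-row tibble with protein/sample/condition counts, scale and
#'   observed-cell fraction.
#' @export
glance.lfq_tbl <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$values),
    n_samples = ncol(x$values),
    n_conditions = length(unique(condition_id(x$design))),
    scale = x$scale,
    prop_observed = mean(!is.na(x$values))
  )
}
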