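#' Remove reverse hits, contaminants, site-only identifications and
#' under-supported protein groups
#'
#' Identification-level filtering: drops rows flagged as reverse-database
#' hits, potential contaminants or "only identified by site", and rows with
#' fewer unique peptides than `config$min_unique_peptides`. Survivor order is
#' preserved. The removal counts per reason are attached as attribute
#' `"removed"`.
#'
#' @param x An `lfq_tbl`.
#' @param config An [analysis_config()].
#' @return The filtered `lfq_tbl`.
#' @export
filter_identifications <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "lfq_tbl"))
  rec <- x$records
  low_pep <- rec$unique_peptides < config$min_unique_peptides
  drop <- rec$is_reverse | rec$is_contaminant | rec$is_only_by_site | low_pep
  out <- subset_proteins(x, !drop)
  attr(out, "removed") <- c(
    reverse = sum(rec$is_reverse),
    contaminant = sum(rec$is_contaminant),
    only_by_site = sum(rec$is_only_by_site),
    low_unique_peptides = sum(low_pep),
    total = sum(drop)
  )
  out
}

#' Keep proteins quantified in at least one condition
#'
#' Retains exactly the proteins with at least
#' `config$min_quantified_per_condition` observed values in at least one
#' condition (fraction x prep). Proteins never reaching that support anywhere
#' cannot be tested nor classified present/absent and are discarded here.
#'
#' @inheritParams filter_identifications
#' @return The filtered `lfq_tbl`.
#' @export
filter_min_quantified <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "lfq_tbl"))
  min_q <- config$min_quantified_per_condition
  if (min_q == 0) return(x)
  cond <- condition_id(x$design)
  too_small <- tapply(rep(1L, length(cond)), cond, sum) < min_q
  if (any(too_small)) {
    warning("condition(s) with fewer samples than min_quantified_per_condition: ",
            paste(names(too_small)[too_small], collapse = ", "))
  }
  counts <- observed_per_condition(x)
  keep <- apply(counts >= min_q, 1, any)
  subset_proteins(x, keep)
}

# proteins x conditions matrix of observed-value counts
observed_per_condition <- function(x) {
  cond <- condition_id(x$design)
  obs <- !is.na(x$values)
  do.call(cbind, lapply(split(seq_along(cond), cond), function(j) {
    rowSums(obs[, j, drop = FALSE])
  }))
}

subset_proteins <- function(x, keep) {
  lfq_table(x$records[keep, , drop = FALSE], x$design,
            x$values[keep, , drop = FALSE], scale = x$scale)
}

#' Log2-transform observed intensities
#'
#' @param x An `lfq_tbl` at raw scale; all observed values must be positive
#'   (zeros encode missing and must already be `NA`).
#' @return The table on the log2 scale; missingness unchanged.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "lfq_tbl"))
  if (x$scale != "raw") stop("table is already on the log2 scale")
  if (any(x$values <= 0, na.rm = TRUE)) {
    stop("observed intensity <= 0; zeros must be recorded as missing before log2")
  }
  lfq_table(x$records, x$design, log2(x$values), scale = "log2")
}

#' Median-center samples within each condition
#'
#' Shifts each sample column by a constant so that, within every condition
#' (fraction x prep), each sample's median of observed values equals the mean
#' of that condition's per-sample medians. Within-sample ordering and pairwise
#' differences are untouched; the operation is idempotent.
#'
#' @param x An `lfq_tbl` on the log2 scale.
#' @return The centered `lfq_tbl`.
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "lfq_tbl"))
  if (x$scale != "log2") stop("median centering expects a log2-scale table")
  vals <- x$values
  med <- apply(vals, 2, stats::median, na.rm = TRUE)
  empty <- !is.finite(med)
  if (any(empty)) {
    stop("sample(s) with no observed values: ",
         paste(x$design$sample_id[empty], collapse = ", "))
  }
  cond <- condition_id(x$design)
  target <- stats::ave(med, cond, FUN = mean)
  vals <- sweep(vals, 2, target - med, `+`)
  lfq_table(x$records, x$design, vals, scale = "log2")
}

#' Partition proteins of one comparison into tested and present/absent classes
#'
#' For one comparison (MBR+ vs one control fraction, within one preparation
#' method), classifies each protein: observed in both conditions ->
#' `"TESTED"`; at least `config$min_quantified_per_condition` observed values
#' in MBR+ and none in the control -> `"PRESENT_ABSENT_PLUS"` (and
#' symmetrically `"PRESENT_ABSENT_CONTROL"`); otherwise (no data in either
#' condition, or detected in only one condition with insufficient support) ->
#' `"DISCARDED"`. The classes are mutually exclusive and exhaustive.
#'
#' @param x A filtered, normalized `lfq_tbl` (log2 scale).
#' @param control_fraction `"MBR_minus"`, `"MBRE"` or `"Total"`.
#' @param prep `"gel"` or `"efasp"`.
#' @param config An [analysis_config()].
#' @return A list of class `lfq_comparison_frame` with the comparison id, the
#'   MBR+/control sub-matrix (still holding `NA`s; see [impute_em()]), a
#'   `status` tibble and the replicate counts.
#' @export
partition_presence_absence <- function(x, control_fraction, prep,
                                       config = analysis_config()) {
  stopifnot(inherits(x, "lfq_tbl"))
  control_fraction <- match.arg(control_fraction, c("MBR_minus", "MBRE", "Total"))
  prep <- match.arg(prep, lfq_preps)
  plus_cols <- which(x$design$fraction == "MBR_plus" & x$design$prep == prep)
  ctrl_cols <- which(x$design$fraction == control_fraction & x$design$prep == prep)
  if (length(plus_cols) == 0 || length(ctrl_cols) == 0) {
    stop(sprintf("design has no samples for MBR_plus/%s or %s/%s",
                 prep, control_fraction, prep))
  }
  obs_plus <- rowSums(!is.na(x$values[, plus_cols, drop = FALSE]))
  obs_ctrl <- rowSums(!is.na(x$values[, ctrl_cols, drop = FALSE]))
  min_q <- config$min_quantified_per_condition
  status <- dplyr::case_when(
    obs_plus > 0 & obs_ctrl > 0 ~ "TESTED",
    obs_ctrl == 0 & obs_plus >= min_q ~ "PRESENT_ABSENT_PLUS",
    obs_plus == 0 & obs_ctrl >= min_q ~ "PRESENT_ABSENT_CONTROL",
    TRUE ~ "DISCARDED"
  )
  structure(
    list(
      comparison_id = paste(control_fraction, prep, sep = "."),
      control_fraction = control_fraction,
      prep = prep,
      block = x$values[, c(plus_cols, ctrl_cols), drop = FALSE],
      n_plus = length(plus_cols),
      n_control = length(ctrl_cols),
      status = tibble::tibble(protein_id = x$records$protein_id, status = status)
    ),
    class = "lfq_comparison_frame"
  )
}

#' @export
print.lfq_comparison_frame <- function(x, ...) {
  cat(sprintf("<lfq_comparison_frame> MBR_plus vs %s (%s): %d + %d samples\n",
              x$control_fraction, x$prep, x$n_plus, x$n_control))
  print(table(x$status$status))
  invisible(x)
}
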