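#' Analysis configuration
#'
#' Bundles every tunable of the enrichment pipeline with validated defaults.
#'
#' @param min_quantified_per_condition Minimum number of observed LFQ values a
#'   protein must reach in at least one condition to be kept (default 2); also
#'   the minimum presence required on the detected side of a present/absent
#'   call.
#' @param fc_threshold_raw Raw-scale fold-change gate (default 1.3). Proteins
#'   whose |log2 fold change| is below `log2(fc_threshold_raw)` are considered
#'   not differentially abundant and are not tested.
#' @param fdr_level Target false-discovery rate for the adaptive
#'   Benjamini-Hochberg procedure (default 0.05).
#' @param absent_rule_min_controls Number of distinct control fractions in
#'   which a protein must be quantitatively absent (while present in MBR+) to
#'   enter the enriched set through the presence/absence branch (default 1;
#'   set to 2 for the stricter variant).
#' @param pi0_method Estimator of the proportion of true null hypotheses:
#'   `"robust"` (min(1, 2 * mean(p))) or `"storey"` (tail estimator at
#'   lambda = 0.5).
#' @param imputation_mode `"conditional_draw"` (a seeded random draw from the
#'   conditional normal of the missing coordinates, the default) or
#'   `"conditional_mean"` (deterministic).
#' @param seed Integer seed driving every stochastic step.
#' @param min_unique_peptides Minimum unique-peptide count for identification
#'   (default 1).
#'
#' @return A list of class `lfq_config`.
#' @export
analysis_config <- function(min_quantified_per_condition = 2,
                            fc_threshold_raw = 1.3,
                            fdr_level = 0.05,
                            absent_rule_min_controls = 1,
                            pi0_method = c("robust", "storey"),
                            imputation_mode = c("conditional_draw", "conditional_mean"),
                            seed = 1L,
                            min_unique_peptides = 1) {
  pi0_method <- match.arg(pi0_method)
  imputation_mode <- match.arg(imputation_mode)
  stopifnot(
    fc_threshold_raw > 1,
    fdr_level > 0, fdr_level < 1,
    min_quantified_per_condition >= 0,
    absent_rule_min_controls >= 1,
    min_unique_peptides >= 0
  )
  structure(
    list(
      min_quantified_per_condition = as.integer(min_quantified_per_condition),
      fc_threshold_raw = fc_threshold_raw,
      fdr_level = fdr_level,
      absent_rule_min_controls = as.integer(absent_rule_min_controls),
      pi0_method = pi0_method,
      imputation_mode = imputation_mode,
      seed = as.integer(seed),
      min_unique_peptides = as.integer(min_unique_peptides)
    ),
    class = "lfq_config"
  )
}

#' @export
print.lfq_config <- function(x, ...) {
  cat("<lfq_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a reproducible 31-bit sub-seed for a named pipeline stage from the
# global seed, so stages are independent but the whole run is driven by one seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
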