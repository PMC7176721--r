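#' Experimental designs for simulation
#'
#' `design_mbr_study()` reproduces the study layout: in-gel digestion with
#' five independent preparations per fraction plus an experimental replicate
#' pair for MBR+/MBR- (six gel replicates for those two fractions), and eFASP
#' with three Total, three MBRE, two MBR+ and two MBR- replicates.
#' `design_single_prep()` builds a balanced one-preparation design (all four
#' fractions, `n_rep` replicates each), convenient for calibration studies.
#'
#' @return A design tibble (`sample_id`, `fraction`, `prep`, `replicate`).
#' @export
design_mbr_study <- function() {
  gel_n <- c(MBR_plus = 6L, MBR_minus = 6L, MBRE = 5L, Total = 5L)
  efasp_n <- c(MBR_plus = 2L, MBR_minus = 2L, MBRE = 3L, Total = 3L)
  build <- function(ns, prep) {
    purrr::imap_dfr(as.list(ns), function(n, fr) {
      tibble::tibble(
        sample_id = sprintf("%s_%s_%d", prep, fr, seq_len(n)),
        fraction = fr, prep = prep, replicate = seq_len(n)
      )
    })
  }
  dplyr::bind_rows(build(gel_n, "gel"), build(efasp_n, "efasp"))
}

#' @rdname design_mbr_study
#' @param n_rep Replicates per fraction (default 5).
#' @param prep Preparation method label (default `"gel"`).
#' @export
design_single_prep <- function(n_rep = 5, prep = "gel") {
  purrr::map_dfr(lfq_fractions, function(fr) {
    tibble::tibble(
      sample_id = sprintf("%s_%s_%d", prep, fr, seq_len(n_rep)),
      fraction = fr, prep = prep, replicate = seq_len(n_rep)
    )
  })
}

#' Simulation parameters
#'
#' Defaults emulate realistic purified-fraction LFQ data: log2 intensities
#' around 25 with a 2-unit protein-to-protein spread, per-protein residual
#' variances from a scaled inverse-chi-square prior (`d0_true = 4`,
#' `s0_sq_true = 0.04`, i.e. a typical residual sd of about 0.2 log2 units),
#' 10% truly enriched proteins with log2 effects uniform on
#' `[log2(1.3), 3]` applied toward MBR+, 5% of proteins entirely absent
#' outside MBR+, left-censored (logistic) intensity-dependent missingness plus
#' a small completely-at-random component.
#'
#' @param m Number of proteins.
#' @param design Design tibble (default [design_mbr_study()]).
#' @param frac_enriched Fraction of truly enriched proteins.
#' @param effect_range_log2 Range of enrichment effects (log2 units).
#' @param baseline_mean,baseline_sd Mean and sd of per-protein baseline log2
#'   abundance.
#' @param d0_true,s0_sq_true Variance-prior truth.
#' @param mnar_midpoint,mnar_slope Logistic left-censor parameters: a cell of
#'   log2 value `v` is censored with probability
#'   `plogis((mnar_midpoint - v) / mnar_slope)`.
#' @param mcar_rate Additional completely-at-random missingness rate.
#' @param frac_absent Fraction of proteins entirely absent outside MBR+.
#' @param seed Integer seed.
#' @return A list of class `lfq_sim_params`.
#' @export
sim_params <- function(m = 2000,
                       design = design_mbr_study(),
                       frac_enriched = 0.10,
                       effect_range_log2 = c(log2(1.3), 3),
                       baseline_mean = 25,
                       baseline_sd = 2,
                       d0_true = 4,
                       s0_sq_true = 0.04,
                       mnar_midpoint = 20,
                       mnar_slope = 1,
                       mcar_rate = 0.02,
                       frac_absent = 0.05,
                       seed = 1L) {
  stopifnot(
    m >= 1,
    frac_enriched >= 0, frac_enriched <= 1,
    length(effect_range_log2) == 2,
    effect_range_log2[1] >= 0, diff(effect_range_log2) >= 0,
    d0_true > 0, s0_sq_true > 0,
    mnar_slope > 0, mcar_rate >= 0, mcar_rate < 1,
    frac_absent >= 0, frac_absent < 1,
    frac_enriched + frac_absent <= 1
  )
  design <- tibble::as_tibble(design)
  if (!any(design$fraction == "MBR_plus")) stop("design must include MBR_plus samples")
  structure(
    list(m = as.integer(m), design = design, frac_enriched = frac_enriched,
         effect_range_log2 = effect_range_log2, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, d0_true = d0_true, s0_sq_true = s0_sq_true,
         mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
         mcar_rate = mcar_rate, frac_absent = frac_absent,
         seed = as.integer(seed)),
    class = "lfq_sim_params"
  )
}

#' Simulate an LFQ dataset with known ground truth
#'
#' Per protein `g`: residual variance `sigma2_g ~ s0_sq_true * d0_true /
#' chisq(d0_true)`; baseline `mu_g ~ Normal(baseline_mean, baseline_sd^2)`;
#' the log2 intensity of sample `s` is `mu_g + effect_g * [s is MBR+] +
#' Normal(0, sigma_g)`. A fraction `frac_enriched` of proteins is truly
#' enriched, with `effect_g` uniform on `effect_range_log2`; a fraction
#' `frac_absent` is entirely masked outside MBR+. Every remaining cell is
#' censored with the intensity-dependent logistic probability, then
#' additionally with probability `mcar_rate`. Raw intensities are
#' `2^log2value`; the run is fully reproducible from `params$seed`.
#'
#' @param params An [sim_params()] object.
#' @return A list of class `lfq_sim`: `table` (an [lfq_table()] at raw scale)
#'   and `truth` (a tibble with `protein_id`, `true_status` in
#'   `NULL`/`ENRICHED`/`ABSENT_IN_CONTROLS`, `true_log2fc`, `true_variance`).
#' @export
simulate_lfq <- function(params = sim_params()) {
  stopifnot(inherits(params, "lfq_sim_params"))
  withr::local_seed(params$seed)
  m <- params$m
  des <- params$design
  n_s <- nrow(des)
  is_plus <- des$fraction == "MBR_plus"

  n_enr <- round(m * params$frac_enriched)
  n_abs <- round(m * params$frac_absent)
  status <- rep("NULL", m)
  pick <- sample.int(m, n_enr + n_abs)
  status[pick[seq_len(n_enr)]] <- "ENRICHED"
  if (n_abs > 0) status[pick[n_enr + seq_len(n_abs)]] <- "ABSENT_IN_CONTROLS"

  sigma2 <- params$s0_sq_true * params$d0_true / stats::rchisq(m, df = params$d0_true)
  mu <- stats::rnorm(m, params$baseline_mean, params$baseline_sd)
  effect <- numeric(m)
  effect[status == "ENRICHED"] <- stats::runif(
    sum(status == "ENRICHED"),
    params$effect_range_log2[1], params$effect_range_log2[2]
  )

  log2v <- matrix(stats::rnorm(m * n_s, sd = rep(sqrt(sigma2), n_s)), m, n_s) +
    mu + outer(effect, as.numeric(is_plus))
  mask_absent <- outer(status == "ABSENT_IN_CONTROLS", !is_plus)
  p_mnar <- stats::plogis((params$mnar_midpoint - log2v) / params$mnar_slope)
  censored <- matrix(stats::runif(m * n_s), m, n_s) < p_mnar
  mcar <- matrix(stats::runif(m * n_s), m, n_s) < params$mcar_rate
  missing <- mask_absent | censored | mcar

  vals <- 2^log2v
  vals[missing] <- NA_real_

  records <- tibble::tibble(
    protein_id = sprintf("P%05d", seq_len(m)),
    gene_name = sprintf("GENE%d", seq_len(m)),
    is_reverse = FALSE, is_contaminant = FALSE, is_only_by_site = FALSE,
    unique_peptides = 1L + stats::rpois(m, 3)
  )
  truth <- tibble::tibble(
    protein_id = records$protein_id,
    true_status = status,
    true_log2fc = effect,
    true_variance = sigma2
  )
  structure(
    list(table = lfq_table(records, des, vals, scale = "raw"), truth = truth),
    class = "lfq_sim"
  )
}

#' Score pipeline calls against simulation truth
#'
#' Compares a merged enriched set to the generator's ground truth. For the
#' overall enriched set, a call is true when the protein is truly `ENRICHED`,
#' or truly `ABSENT_IN_CONTROLS` *and* carried by an `ABSENT_IN` reason (the
#' absence branch); otherwise it is false. For the differential branch
#' (proteins with at least one `DIFFERENTIAL` reason), a call is false exactly
#' when the protein is truly null.
#'
#' @param truth Truth tibble from [simulate_lfq()].
#' @param merged Merged-record tibble from [compose_enriched_set()].
#' @return A one-row tibble: overall `n_called`, `n_false`, `fdp`, `tpr`, and
#'   the differential branch's `n_called_diff`, `n_false_diff`,
#'   `fdp_differential`.
#' @export
evaluate_calls <- function(truth, merged) {
  if (!all(merged$protein_id %in% truth$protein_id)) {
    stop("merged records contain proteins outside the truth universe")
  }
  # proteins filtered out upstream are simply never called
  m <- dplyr::left_join(merged, truth, by = "protein_id")
  has_tag <- function(reasons, prefix) {
    vapply(reasons, function(r) any(startsWith(r, prefix)), logical(1))
  }
  called <- m$enriched
  via_diff <- has_tag(m$reasons, "DIFFERENTIAL:")
  via_abs <- has_tag(m$reasons, "ABSENT_IN:")
  true_call <- m$true_status == "ENRICHED" |
    (m$true_status == "ABSENT_IN_CONTROLS" & via_abs)
  n_called <- sum(called)
  n_false <- sum(called & !true_call)
  n_nonnull <- sum(truth$true_status != "NULL")
  n_called_diff <- sum(via_diff)
  n_false_diff <- sum(via_diff & m$true_status == "NULL")
  tibble::tibble(
    n_called = n_called,
    n_false = n_false,
    fdp = n_false / max(1, n_called),
    tpr = sum(called & true_call & m$true_status != "NULL") / max(1, n_nonnull),
    n_called_diff = n_called_diff,
    n_false_diff = n_false_diff,
    fdp_differential = n_false_diff / max(1, n_called_diff)
  )
}
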