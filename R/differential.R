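#' Two-group summaries of a completed comparison block
#'
#' Means per group, log2 fold change (MBR+ minus control) and the pooled
#' within-group variance feeding the moderated t-test.
#'
#' @param block Complete numeric matrix (no `NA`), columns ordered MBR+ then
#'   control.
#' @param n_plus,n_control Number of MBR+ / control columns (each >= 2).
#' @return A tibble with `mean_plus`, `mean_control`, `log2fc`, `s2` (pooled
#'   variance) and `df` (residual degrees of freedom, `n_plus + n_control - 2`).
#' @export
group_stats <- function(block, n_plus, n_control) {
  block <- as.matrix(block)
  stopifnot(ncol(block) == n_plus + n_control)
  if (n_plus < 2 || n_control < 2) {
    stop("each group needs at least 2 samples for a pooled variance")
  }
  if (anyNA(block)) stop("block must be complete (impute first)")
  ip <- seq_len(n_plus)
  ic <- n_plus + seq_len(n_control)
  mp <- rowMeans(block[, ip, drop = FALSE])
  mc <- rowMeans(block[, ic, drop = FALSE])
  ssp <- rowSums((block[, ip, drop = FALSE] - mp)^2)
  ssc <- rowSums((block[, ic, drop = FALSE] - mc)^2)
  df <- n_plus + n_control - 2
  tibble::tibble(
    mean_plus = mp,
    mean_control = mc,
    log2fc = mp - mc,
    s2 = (ssp + ssc) / df,
    df = df
  )
}

#' Apply the fold-change gate
#'
#' Proteins whose absolute log2 fold change is below
#' `log2(config$fc_threshold_raw)` are considered not differentially abundant
#' and are excluded from statistical testing (both directions are gated;
#' the enrichment direction is enforced later, at set composition).
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param config An [analysis_config()].
#' @return Logical vector: `TRUE` = passes the gate (is tested).
#' @export
fold_change_gate <- function(log2fc, config = analysis_config()) {
  abs(log2fc) >= log2(config$fc_threshold_raw)
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq` of a
#' scaled inverse-chi-square prior on the per-protein variances, by matching
#' the first two moments of `log(s2)` to those implied by a scaled-F
#' distribution: with `z = log(s2)` and `e = z - digamma(df/2) + log(df/2)`,
#' solve `trigamma(d0/2) = mean((e - mean(e))^2 * m/(m-1) - trigamma(df/2))`
#' by Newton inversion of the trigamma function, and
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. A non-positive
#' trigamma argument means no excess spread beyond sampling noise:
#' `d0 = Inf` with `s0_sq` the mean of the variances.
#'
#' @param s2 Per-protein residual variances (zeros are excluded from the fit).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return A list of class `lfq_moderation_fit`: `d0`, `s0_sq`, `s2`, `df`,
#'   `n_used`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(ok) < 2) stop("need at least 2 positive variances to fit the prior")
  z <- log(s2[ok])
  dg <- df[ok]
  e <- z - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  m <- length(e)
  v <- mean((e - ebar)^2 * m / (m - 1) - trigamma(dg / 2))
  if (v <= 0) {
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  } else {
    half_d0 <- trigamma_inverse(v)
    d0 <- 2 * half_d0
    s0_sq <- exp(ebar + digamma(half_d0) - log(half_d0))
  }
  structure(
    list(d0 = d0, s0_sq = s0_sq, s2 = s2, df = df, n_used = m),
    class = "lfq_moderation_fit"
  )
}

# Newton inversion of trigamma (decreasing, convex on (0, Inf)).
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' @export
print.lfq_moderation_fit <- function(x, ...) {
  cat(sprintf("<lfq_moderation_fit> d0 = %s, s0_sq = %.4g (fit on %d variances)\n",
              format(x$d0), x$s0_sq, x$n_used))
  invisible(x)
}

#' @export
glance.lfq_moderation_fit <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, n_used = x$n_used)
}

#' Moderated t-statistics
#'
#' Shrinks each protein's variance toward the prior,
#' `s_tilde^2 = (d0 * s0_sq + df * s2) / (d0 + df)` (the limit `s0_sq` when
#' `d0 = Inf`), and tests `log2fc` against a Student t with `d0 + df` degrees
#' of freedom (standard normal when infinite). `d0 = 0` reproduces the
#' ordinary pooled two-sample t-test.
#'
#' @param stats Tibble from [group_stats()] (needs `log2fc`, `s2`, `df`).
#' @param fit An `lfq_moderation_fit` (or a list with `d0`, `s0_sq`).
#' @param n_plus,n_control Group sizes.
#' @return `stats` with added columns `t_mod`, `df_total`, `p` (two-sided).
#' @export
moderated_t <- function(stats, fit, n_plus, n_control) {
  d0 <- fit$d0
  s0_sq <- fit$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) {
    rep(s0_sq, nrow(stats))
  } else {
    (d0 * s0_sq + stats$df * stats$s2) / (d0 + stats$df)
  }
  if (any(s_tilde_sq <= 0)) {
    stop("degenerate zero posterior variance; cannot compute a moderated t")
  }
  se <- sqrt(s_tilde_sq * (1 / n_plus + 1 / n_control))
  t_mod <- stats$log2fc / se
  df_total <- d0 + stats$df
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  # extreme statistics underflow the t tail; keep p strictly positive so
  # downstream log-based steps (pi0, Fisher) stay defined
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  dplyr::mutate(stats, t_mod = t_mod, df_total = df_total, p = p)
}

#' Estimate the proportion of true null hypotheses
#'
#' `"robust"` (default): `min(1, 2 * mean(p))` — conservative mean-based
#' estimator. `"storey"`: tail estimator `#\{p > 0.5\} / (m * 0.5)`, capped at
#' 1 and floored at `1/m` so the adaptive procedure never degenerates.
#'
#' @param p Vector of p-values in (0, 1].
#' @param method `"robust"` or `"storey"`.
#' @return A single value in (0, 1].
#' @export
estimate_pi0 <- function(p, method = c("robust", "storey")) {
  method <- match.arg(method)
  if (length(p) == 0) stop("cannot estimate pi0 from an empty p-value list")
  stopifnot(all(p > 0 & p <= 1))
  pi0 <- switch(method,
    robust = min(1, 2 * mean(p)),
    storey = min(1, mean(p > 0.5) / 0.5)
  )
  max(pi0, 1 / length(p))
}

#' Adaptive Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values scaled by an estimated proportion of true nulls:
#' `p_adj(i) = min over j >= i (sorted) of min(1, pi0 * m * p(j) / j)`. With
#' `pi0 = 1` this is exactly the standard Benjamini-Hochberg adjustment.
#'
#' @param p Vector of p-values in (0, 1].
#' @param pi0 Proportion of true nulls in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
adaptive_bh <- function(p, pi0 = 1) {
  stopifnot(pi0 > 0, pi0 <= 1)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(pi0 * m / (m:1) * p[o]))[ro]
}

#' Run one complete MBR+ vs control comparison
#'
#' Chains, on a partitioned comparison frame: EM imputation of the tested
#' block, group summaries, the fold-change gate, the variance-prior fit (on
#' the gated set), moderated t-tests, pi0 estimation and adaptive
#' Benjamini-Hochberg. `significant` flags proteins differentially abundant in
#' either direction at `fdr_level`; `significant_enriched` additionally
#' requires enrichment toward MBR+ (`log2fc >= log2(fc_threshold_raw)`).
#'
#' @param frame An `lfq_comparison_frame` from [partition_presence_absence()].
#' @param config An [analysis_config()].
#' @return A tibble of class `lfq_comparison` with one row per protein:
#'   `protein_id`, `status` (`TESTED`, `FC_FILTERED`, `PRESENT_ABSENT_PLUS`,
#'   `PRESENT_ABSENT_CONTROL`, `DISCARDED`), `log2fc`, `t_mod`, `df_total`,
#'   `p`, `p_adj`, `significant`, `significant_enriched`; fit metadata (`d0`,
#'   `s0_sq`, `pi0`, replicate counts) in attribute `"meta"`.
#' @export
run_comparison <- function(frame, config = analysis_config()) {
  stopifnot(inherits(frame, "lfq_comparison_frame"))
  res <- dplyr::mutate(
    frame$status,
    log2fc = NA_real_, t_mod = NA_real_, df_total = NA_real_,
    p = NA_real_, p_adj = NA_real_,
    significant = FALSE, significant_enriched = FALSE
  )
  meta <- list(
    comparison_id = frame$comparison_id,
    control_fraction = frame$control_fraction,
    prep = frame$prep,
    n_plus = frame$n_plus, n_control = frame$n_control,
    d0 = NA_real_, s0_sq = NA_real_, pi0 = NA_real_,
    pi0_method = config$pi0_method,
    n_tested = 0L, n_gated = 0L
  )
  tested <- which(frame$status$status == "TESTED")
  meta$n_tested <- length(tested)
  if (length(tested) > 0 && frame$n_plus >= 2 && frame$n_control >= 2) {
    block <- impute_em(
      frame$block[tested, , drop = FALSE],
      seed = derive_seed(config$seed, paste0("impute.", frame$comparison_id)),
      mode = config$imputation_mode
    )
    st <- group_stats(block, frame$n_plus, frame$n_control)
    res$log2fc[tested] <- st$log2fc
    gate <- fold_change_gate(st$log2fc, config)
    res$status[tested][!gate] <- "FC_FILTERED"
    meta$n_gated <- sum(gate)
    if (sum(gate) >= 2 && any(st$s2[gate] > 0)) {
      fit <- fit_variance_prior(st$s2[gate], st$df[gate])
      mt <- moderated_t(st[gate, ], fit, frame$n_plus, frame$n_control)
      pi0 <- estimate_pi0(mt$p, config$pi0_method)
      padj <- adaptive_bh(mt$p, pi0)
      idx <- tested[gate]
      res$t_mod[idx] <- mt$t_mod
      res$df_total[idx] <- mt$df_total
      res$p[idx] <- mt$p
      res$p_adj[idx] <- padj
      res$significant[idx] <- padj < config$fdr_level
      res$significant_enriched[idx] <- padj < config$fdr_level &
        mt$log2fc >= log2(config$fc_threshold_raw)
      meta$d0 <- fit$d0
      meta$s0_sq <- fit$s0_sq
      meta$pi0 <- pi0
    } else {
      warning(sprintf("comparison %s: fewer than 2 testable proteins after the fold-change gate; statuses reported without tests",
                      frame$comparison_id))
    }
  }
  attr(res, "meta") <- meta
  class(res) <- c("lfq_comparison", class(res))
  res
}

#' @export
tidy.lfq_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.lfq_comparison <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble::tibble(
    comparison_id = meta$comparison_id,
    n_plus = meta$n_plus, n_control = meta$n_control,
    n_tested = meta$n_tested, n_gated = meta$n_gated,
    d0 = meta$d0, s0_sq = meta$s0_sq, pi0 = meta$pi0,
    pi0_method = meta$pi0_method,
    n_significant = sum(x$significant, na.rm = TRUE),
    n_significant_enriched = sum(x$significant_enriched, na.rm = TRUE),
    n_present_absent_plus = sum(x$status == "PRESENT_ABSENT_PLUS")
  )
}
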