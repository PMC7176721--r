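test_that("group summaries match hand arithmetic", {
  block <- rbind(
    c(1, 2, 3, 3, 4, 5),
    c(1, 2, 3, 1, 2, 3),
    c(2, 2, 2, 5, 5, 5)
  )
  st <- group_stats(block, 3, 3)
  expect_equal(st$log2fc, c(-2, 0, -3))
  expect_equal(st$s2, c(1, 1, 0))
  expect_equal(st$df, c(4, 4, 4))
  expect_error(group_stats(block[, c(1, 4, 5, 6)], 1, 3), "at least 2")
  expect_error(group_stats(rbind(c(1, NA, 2, 3)), 2, 2), "complete")
})

test_that("the fold-change gate is a magnitude rule at log2(threshold)", {
  cfg <- analysis_config(fc_threshold_raw = 1.3)
  expect_false(fold_change_gate(0.2, cfg))        # 0.2 < log2(1.3) ~ 0.3785
  expect_true(fold_change_gate(-1, cfg))          # both directions pass
  expect_equal(fold_change_gate(c(0.38, -0.38, 0.37), cfg),
               c(TRUE, TRUE, FALSE))
  cfg1 <- analysis_config(fc_threshold_raw = 1 + 1e-12)  # near-vacuous threshold
  expect_equal(fold_change_gate(c(0, 0.01, -5), cfg1), c(FALSE, TRUE, TRUE))
})

test_that("variance-prior fit recovers simulated hyperparameters and handles edge cases", {
  # recovery: sigma2 ~ s0^2 d0 / chisq(d0), s2 | sigma2 ~ sigma2 chisq(dg)/dg
  withr::local_seed(123)
  m <- 5000; d0 <- 4; s0 <- 1; dg <- 4
  sigma2 <- s0 * d0 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, dg) / dg
  fit <- fit_variance_prior(s2, dg)
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.1)

  # identical variances: degenerate zero-spread case
  fit0 <- fit_variance_prior(rep(0.5, 10), 4)
  expect_true(is.infinite(fit0$d0))
  expect_equal(fit0$s0_sq, 0.5)

  # two very different variances: finite positive d0
  fit2 <- fit_variance_prior(c(0.01, 10), 4)
  expect_true(is.finite(fit2$d0) && fit2$d0 > 0)

  expect_error(fit_variance_prior(c(0, 0), 4), "positive variances")
})

test_that("variance shrinkage and prior fit agree with the limma cross-check", {
  skip_if_not_installed("limma")
  withr::local_seed(7)
  s2 <- 0.05 * 4 / rchisq(400, 4) * rchisq(400, 6) / 6
  fit <- fit_variance_prior(s2, 6)
  sv <- limma::squeezeVar(s2, df = 6)
  expect_equal(fit$d0, sv$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_sq, sv$var.prior, tolerance = 1e-6)
  st <- tibble::tibble(log2fc = rnorm(400), s2 = s2, df = 6)
  mt <- moderated_t(st, fit, 4, 4)
  s_tilde <- (fit$d0 * fit$s0_sq + 6 * s2) / (fit$d0 + 6)
  expect_equal(s_tilde, sv$var.post, tolerance = 1e-6)
})

test_that("moderated t matches hand arithmetic and its two limits", {
  st <- tibble::tibble(log2fc = -2, s2 = 1, df = 4)
  mt <- moderated_t(st, list(d0 = 4, s0_sq = 1), 3, 3)
  expect_equal(mt$t_mod, -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(mt$df_total, 8)
  expect_equal(mt$p, 2 * pt(-abs(-2 / sqrt(2 / 3)), 8), tolerance = 1e-12)

  # d0 = 0: exactly the ordinary pooled two-sample t (oracle: stats::t.test)
  withr::local_seed(5)
  g1 <- rnorm(4, 10); g2 <- rnorm(5, 11)
  block <- rbind(c(g1, g2))
  stats0 <- group_stats(block, 4, 5)
  mt0 <- moderated_t(stats0, list(d0 = 0, s0_sq = 1), 4, 5)
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(mt0$t_mod, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(mt0$p, tt$p.value, tolerance = 1e-10)
  expect_equal(mt0$df_total, unname(tt$parameter))

  # d0 = Inf: z-test with the prior variance
  mtI <- moderated_t(stats0, list(d0 = Inf, s0_sq = 0.8), 4, 5)
  z <- stats0$log2fc / sqrt(0.8 * (1 / 4 + 1 / 5))
  expect_equal(mtI$t_mod, z, tolerance = 1e-12)
  expect_equal(mtI$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("pi0 estimators follow their formulas and are sane under uniform nulls", {
  expect_equal(estimate_pi0(rep(1, 5)), 1)
  expect_equal(estimate_pi0(c(0.1, 0.2, 0.9)), 0.8)
  expect_equal(estimate_pi0(c(0.1, 0.2, 0.3, 0.9), "storey"), 0.5)
  withr::local_seed(99)
  p <- runif(10000)
  expect_lt(abs(estimate_pi0(p, "robust") - 1), 0.05)
  expect_lt(abs(estimate_pi0(p, "storey") - 1), 0.05)
  expect_error(estimate_pi0(numeric(0)), "empty")
})

test_that("adaptive BH reproduces the hand example and the brute-force/stats oracles", {
  expect_equal(adaptive_bh(c(0.01, 0.02, 0.04), 1), c(0.03, 0.03, 0.04))
  expect_equal(adaptive_bh(0.37, 1), 0.37)

  withr::local_seed(21)
  for (m in c(1, 2, 3, 5, 12, 20)) {
    p <- round(runif(m), 3) + 1e-4
    expect_equal(adaptive_bh(p, 1), bf_step_up(p), tolerance = 1e-12)
    expect_equal(adaptive_bh(p, 1), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # exhaustive orderings for a small vector: permutation invariance per element
  p4 <- c(0.011, 0.22, 0.049, 0.9)
  perms <- list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))
  base <- adaptive_bh(p4, 1)
  for (pr in perms) {
    expect_equal(adaptive_bh(p4[pr], 1), base[pr], tolerance = 1e-14)
    expect_equal(adaptive_bh(p4[pr], 1), bf_step_up(p4[pr]), tolerance = 1e-14)
  }
  # monotone in p, bounded by 1, and >= pi0 * p
  p <- runif(50)
  adj <- adaptive_bh(p, 0.7)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= 0.7 * p - 1e-12))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("a full comparison flags constructed strong effects and only those", {
  withr::local_seed(31)
  m <- 100
  block <- matrix(rnorm(m * 10, sd = 0.05), m, 10) + 20
  block[1:3, 1:5] <- block[1:3, 1:5] + c(2, 2.5, 3)  # enriched toward MBR+
  rownames(block) <- sprintf("P%04d", seq_len(m))
  frame <- frame_from_matrix(block, 5, 5)
  res <- run_comparison(frame, analysis_config(seed = 31))
  expect_setequal(res$protein_id[res$significant_enriched],
                  sprintf("P%04d", 1:3))
  meta <- attr(res, "meta")
  expect_equal(meta$n_tested, m)
  expect_true(all(res$status[4:m] %in% c("FC_FILTERED", "TESTED")))

  # every protein failing the gate: statuses only, no tests, with a warning
  block0 <- matrix(rnorm(m * 10, sd = 0.01), m, 10) + 20
  rownames(block0) <- sprintf("P%04d", seq_len(m))
  expect_warning(res0 <- run_comparison(frame_from_matrix(block0, 5, 5),
                                        analysis_config(seed = 1)),
                 "fold-change gate")
  expect_true(all(res0$status == "FC_FILTERED"))
  expect_true(all(is.na(res0$p)))
})

test_that("pure-null runs of the testing machinery make no calls (no-gate form)", {
  # with the fold-change gate disabled there is no selection before testing;
  # adaptive BH then makes zero calls in (at least) 19 of 20 seeded pure-null runs
  zero_calls <- vapply(1:20, function(s) {
    p <- sim_params(m = 200, design = design_single_prep(5), frac_enriched = 0,
                    frac_absent = 0, mcar_rate = 0, mnar_midpoint = -1000,
                    seed = s)
    sim <- simulate_lfq(p)
    cfg <- analysis_config(seed = s, fc_threshold_raw = 1 + 1e-9)
    tbl <- median_center(log2_transform(sim$table))
    frame <- partition_presence_absence(tbl, "Total", "gel", cfg)
    res <- suppressWarnings(run_comparison(frame, cfg))
    sum(res$significant) == 0
  }, logical(1))
  expect_gte(mean(zero_calls), 0.95)
})

test_that("power rises with the true effect size and the replicate count", {
  tpr_at <- function(effect, n_rep, seeds = 1:3) {
    mean(vapply(seeds, function(s) {
      p <- sim_params(m = 400, design = design_single_prep(n_rep),
                      frac_enriched = 0.1, frac_absent = 0,
                      effect_range_log2 = c(effect, effect), seed = s)
      sim <- simulate_lfq(p)
      cfg <- analysis_config(seed = s)
      tbl <- median_center(log2_transform(sim$table))
      frame <- partition_presence_absence(tbl, "Total", "gel", cfg)
      res <- suppressWarnings(run_comparison(frame, cfg))
      enriched_true <- sim$truth$protein_id[sim$truth$true_status == "ENRICHED"]
      mean(enriched_true %in% res$protein_id[res$significant_enriched])
    }, numeric(1)))
  }
  expect_gte(tpr_at(2, 5), tpr_at(0.6, 5))
  expect_gte(tpr_at(1, 5), tpr_at(1, 3))
})
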