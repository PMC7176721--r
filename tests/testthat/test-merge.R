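test_that("Fisher merging matches its chi-square closed forms", {
  expect_equal(fisher_merge(0.05), 0.05, tolerance = 1e-12)      # k = 1 identity
  x2 <- -2 * (log(0.1) + log(0.2))
  expect_equal(fisher_merge(c(0.1, 0.2)), exp(-x2 / 2) * (1 + x2 / 2),
               tolerance = 1e-12)                                # k = 2 closed form
  expect_equal(fisher_merge(c(1, 1, 1)), 1)
  expect_true(is.na(fisher_merge(numeric(0))))
  expect_true(is.na(fisher_merge(NA_real_)))                     # missing omitted
  expect_error(fisher_merge(c(0.5, 0)), "p > 0")

  # permutation invariance and strict monotonicity in each input
  ps <- c(0.3, 0.07, 0.51)
  expect_equal(fisher_merge(ps), fisher_merge(rev(ps)), tolerance = 1e-15)
  expect_lt(fisher_merge(c(0.05, 0.3)), fisher_merge(c(0.1, 0.3)))
})

test_that("max log2FC takes the signed maximum over available comparisons", {
  expect_equal(max_log2fc(c(0.5, 2.1, -0.3)), 2.1)
  expect_equal(max_log2fc(-1), -1)
  expect_equal(max_log2fc(c(0.5, NA, 2.1, NA, -0.3, 1)), 2.1)
  expect_true(is.na(max_log2fc(c(NA_real_, NA_real_))))
})

# hand-built comparison results covering the composition rules
fake_comparison <- function(cid, fraction, tbl) {
  res <- tibble::as_tibble(tbl)
  attr(res, "meta") <- list(comparison_id = cid, control_fraction = fraction,
                            prep = sub(".*\\.", "", cid), n_plus = 5, n_control = 5)
  class(res) <- c("lfq_comparison", class(res))
  res
}

row_of <- function(pid, status = "TESTED", log2fc = NA_real_, p = NA_real_,
                   sig = FALSE, sig_enr = FALSE) {
  tibble::tibble(protein_id = pid, status = status, log2fc = log2fc,
                 t_mod = NA_real_, df_total = NA_real_, p = p,
                 p_adj = NA_real_, significant = sig, significant_enriched = sig_enr)
}

test_that("enriched-set composition follows the differential and absence branches", {
  # A: significant_enriched in Total.gel only
  # B: PRESENT_ABSENT_PLUS vs MBR_minus.efasp only
  # C: small FC everywhere, data in both conditions -> not enriched
  # D: PRESENT_ABSENT_PLUS vs the same fraction in both preps (counts once)
  cmp1 <- fake_comparison("Total.gel", "Total", dplyr::bind_rows(
    row_of("A", log2fc = 2, p = 1e-5, sig = TRUE, sig_enr = TRUE),
    row_of("B", "DISCARDED"),
    row_of("C", log2fc = 0.1, status = "FC_FILTERED"),
    row_of("D", "PRESENT_ABSENT_PLUS")
  ))
  cmp2 <- fake_comparison("MBR_minus.efasp", "MBR_minus", dplyr::bind_rows(
    row_of("A", log2fc = 0.5, p = 0.4),
    row_of("B", "PRESENT_ABSENT_PLUS"),
    row_of("C", log2fc = -0.2, status = "FC_FILTERED"),
    row_of("D", "TESTED", log2fc = 1, p = 0.2)
  ))
  cmp3 <- fake_comparison("MBR_minus.gel", "MBR_minus", dplyr::bind_rows(
    row_of("A", log2fc = 1.4, p = 0.03),
    row_of("B", "DISCARDED"),
    row_of("C", log2fc = 0.05, status = "FC_FILTERED"),
    row_of("D", "PRESENT_ABSENT_PLUS")
  ))
  merged <- compose_enriched_set(list(`Total.gel` = cmp1,
                                      `MBR_minus.efasp` = cmp2,
                                      `MBR_minus.gel` = cmp3),
                                 analysis_config())
  m <- function(pid) merged[merged$protein_id == pid, ]
  expect_true(m("A")$enriched)
  expect_equal(m("A")$reasons[[1]], "DIFFERENTIAL:Total.gel")
  expect_equal(m("A")$max_log2fc, 2)
  expect_equal(m("A")$merged_p, fisher_merge(c(1e-5, 0.4, 0.03)), tolerance = 1e-12)
  expect_equal(m("A")$n_comparisons_available, 3)
  expect_equal(m("A")$n_significant_fractions, 1)

  expect_true(m("B")$enriched)
  expect_equal(m("B")$reasons[[1]], "ABSENT_IN:MBR_minus.efasp")
  expect_true(is.na(m("B")$max_log2fc))
  expect_true(is.na(m("B")$merged_p))
  expect_equal(m("B")$n_comparisons_available, 1)

  expect_false(m("C")$enriched)
  expect_length(m("C")$reasons[[1]], 0)

  # D is absent vs MBR_minus in both preps: one distinct fraction; with the
  # stricter two-fraction rule it is no longer enriched
  expect_true(m("D")$enriched)
  expect_setequal(m("D")$reasons[[1]],
                  c("ABSENT_IN:Total.gel", "ABSENT_IN:MBR_minus.gel"))
  strict <- compose_enriched_set(list(`Total.gel` = cmp1,
                                      `MBR_minus.efasp` = cmp2,
                                      `MBR_minus.gel` = cmp3),
                                 analysis_config(absent_rule_min_controls = 2))
  expect_true(strict[strict$protein_id == "D", ]$enriched)   # Total + MBR_minus = 2 fractions
  expect_false(strict[strict$protein_id == "B", ]$enriched)  # only MBR_minus
})

test_that("UpSet counts are exclusive and sum to the union", {
  counts <- upset_counts(list(s1 = c("A", "B"), s2 = c("B", "C")))
  get <- function(combo) counts$count[counts$combination == combo]
  expect_equal(get("s1"), 1)
  expect_equal(get("s2"), 1)
  expect_equal(get("s1&s2"), 1)
  expect_equal(sum(counts$count), 3)

  disj <- upset_counts(list(a = c("x", "y"), b = c("z")))
  expect_equal(disj$count[disj$combination == "a&b"], 0)
  expect_equal(sum(disj$count), 3)

  ident <- upset_counts(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(ident$count[ident$combination == "a&b"], 2)
  expect_equal(sum(ident$count[ident$degree == 1]), 0)

  # property: exclusive counts always sum to |union|
  withr::local_seed(8)
  sets <- lapply(1:4, function(i) sample(LETTERS, sample(3:10, 1)))
  names(sets) <- paste0("c", 1:4)
  expect_equal(sum(upset_counts(sets)$count), length(unique(unlist(sets))))
})

test_that("list overlap returns intersection size and recovered fraction", {
  ov <- overlap_with_list(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$fraction_of_external, 2 / 3)
  expect_equal(overlap_with_list(c("a", "b"), c("a", "b"))$fraction_of_external, 1)
  expect_equal(overlap_with_list(c("a"), c("b", "c"))$n_overlap, 0)
  expect_error(overlap_with_list(c("a"), character(0)), "empty")
})
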