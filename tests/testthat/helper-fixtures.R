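# Small in-code fixtures shared across test files.

# A 4-sample, one-prep design: 2 x MBR_plus, 2 x Total (gel).
tiny_design <- function() {
  tibble::tibble(
    sample_id = c("g_plus_1", "g_plus_2", "g_tot_1", "g_tot_2"),
    fraction = c("MBR_plus", "MBR_plus", "Total", "Total"),
    prep = "gel",
    replicate = c(1L, 2L, 1L, 2L)
  )
}

tiny_records <- function(n, prefix = "P") {
  tibble::tibble(
    protein_id = paste0(prefix, seq_len(n)),
    gene_name = paste0("G", seq_len(n)),
    is_reverse = FALSE,
    is_contaminant = FALSE,
    is_only_by_site = FALSE,
    unique_peptides = 2L
  )
}

# Write a MaxQuant-dialect protein-groups file; `values` is a proteins x
# samples matrix on the raw scale with 0 = not detected.
write_tiny_pg <- function(values, design = tiny_design(), records = NULL,
                          path = tempfile(fileext = ".tsv")) {
  n <- nrow(values)
  if (is.null(records)) records <- tiny_records(n)
  header <- c("Majority protein IDs", "Gene names", "Reverse",
              "Potential contaminant", "Only identified by site",
              "Peptide counts (unique)",
              paste("LFQ intensity", design$sample_id))
  flag <- function(b) ifelse(b, "+", "")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(records$protein_id[i], records$gene_name[i],
            flag(records$is_reverse[i]), flag(records$is_contaminant[i]),
            flag(records$is_only_by_site[i]),
            as.character(records$unique_peptides[i]),
            format(values[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

# A complete comparison frame built directly from a matrix (MBR+ columns
# first), bypassing file IO.
frame_from_matrix <- function(block, n_plus, n_control,
                              control_fraction = "Total", prep = "gel") {
  structure(
    list(
      comparison_id = paste(control_fraction, prep, sep = "."),
      control_fraction = control_fraction,
      prep = prep,
      block = block,
      n_plus = n_plus,
      n_control = n_control,
      status = tibble::tibble(
        protein_id = if (is.null(rownames(block))) {
          sprintf("P%04d", seq_len(nrow(block)))
        } else {
          rownames(block)
        },
        status = ifelse(
          rowSums(!is.na(block[, seq_len(n_plus), drop = FALSE])) > 0 &
            rowSums(!is.na(block[, n_plus + seq_len(n_control), drop = FALSE])) > 0,
          "TESTED", "DISCARDED"
        )
      )
    ),
    class = "lfq_comparison_frame"
  )
}

# Brute-force step-up adjusted p-values: literal "min over j >= i in sorted
# order of min(1, m p_(j) / j)", written as an explicit double loop.
bf_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- 1
    for (j in i:m) cand <- min(cand, m * ps[j] / j)
    adj[i] <- cand
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail by direct enumeration of the pmf.
enum_hyper_upper <- function(k, K, n, N) {
  xs <- max(0, n + K - N):min(n, K)
  pm <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(pm[xs >= k])
}
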