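---
title: "Methods: differential enrichment for fraction proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enrichment for fraction proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqenrich)
```

## The statistical model

`lfqenrich` decides which proteins are enriched in a purified fraction
(MBR+) relative to three control fractions (MBR−, MBRE, Total), measured by
label-free quantification with two preparation methods (in-gel digestion,
five independent preparations per fraction plus an experimental replicate
pair for MBR+/MBR−; eFASP, 3/3/2/2 replicates). The two preparations are
never mixed: a *condition* is always a fraction × preparation pair, and the
analysis consists of six independent MBR+ vs control comparisons.

Within one comparison, log2 LFQ intensities of protein $g$ are modeled as

$$y_{gs} = \mu_g + \beta_g\,[s \in \text{MBR+}] + \varepsilon_{gs},
  \qquad \varepsilon_{gs} \sim N(0, \sigma^2_g),$$

with a scaled inverse-chi-square prior on the residual variances,
$\sigma^2_g \sim s_0^2\, d_0 / \chi^2_{d_0}$. Non-detection is frequent and
partly intensity-dependent, so the matrix carries an explicit missingness
mask and every step distinguishes observed from missing cells.

## Pipeline steps and the reasoning behind them

**Identification filters.** Reverse hits, potential contaminants and
"only identified by site" entries are removed, and at least one unique
peptide is required. Parsing never drops rows; filtering is a separate,
counted step so the run manifest can account for every protein.

**Quantification filter.** A protein is kept when it has at least
`min_quantified_per_condition` (default 2) observed values in *at least one*
condition. The alternative reading — requiring two values in *every*
condition — would leave no protein with an empty condition and would make the
subsequent presence/absence classification vacuous, so the package adopts
the coherent reading and exposes the threshold in `analysis_config()`.

**Median centering.** Within each condition, every sample is shifted so its
median of observed values equals the mean of the condition's per-sample
medians. Any common per-condition target would give identical downstream
log-ratios; the mean-of-medians target keeps the condition's overall level
unchanged and makes the operation idempotent.

**Presence/absence partition.** Per comparison, proteins with zero observed
values in exactly one of the two conditions and sufficient support
(≥ `min_quantified_per_condition` values) on the other side are set aside as
`PRESENT_ABSENT_PLUS` / `PRESENT_ABSENT_CONTROL`; proteins with data on both
sides are `TESTED`; the remainder is `DISCARDED` for that comparison. The
classes are mutually exclusive and exhaustive.

**EM imputation.** For the tested block of one comparison (proteins ×
MBR+/control samples), a multivariate normal over the sample columns is
fitted by expectation–maximization, grouping rows by missingness pattern.
Missing cells are then filled either by one random draw from the conditional
normal of the missing coordinates given the observed ones (default,
seeded — matching the single stochastic imputation of the normal-model
tradition) or by the conditional mean (deterministic option). Fitting is per
comparison on the tested block only, mirroring the order of operations:
present/absent proteins are set aside first, then missing values are
imputed. Numerical choices: convergence at a relative log-likelihood change
below 1e−6, at most 500 iterations (an error reports the last change
otherwise), and a ridge of 1e−6 × mean diagonal, escalated tenfold up to
four times, if a covariance sub-matrix is singular. Observed cells are
returned bit-identically, and the observed-data log-likelihood is
non-decreasing over iterations — both are tested properties. Fully missing
rows contribute nothing to the fit and are filled from the marginal.

**Fold-change gate.** Proteins with $|\log_2 \text{FC}| < \log_2 1.3$ are
declared not differentially abundant and are not tested. The gate is
magnitude-based (both directions pass) because the merged volcano displays
both tails; the enrichment *direction* (toward MBR+) is enforced later, when
the enriched set is composed. Fold change is the difference of log2 group
means — all modeling happens on the log2 scale after imputation.

**Moderated t-test.** The prior $(d_0, s_0^2)$ is fitted on the gated set of
each comparison by matching the first two moments of $\log s^2_g$ to a
scaled-F distribution, inverting the trigamma function by Newton's method.
When the excess spread is non-positive the prior is degenerate
($d_0 = \infty$) and $s_0^2$ is the mean variance. The posterior variance
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ gives
$t_g = \log_2\text{FC}_g \big/ \sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}$ on
$d_0 + d_g$ degrees of freedom; $d_0 = 0$ reproduces the ordinary pooled
t-test and $d_0 = \infty$ a z-test — both limits are tested to 1e−10, and
the fit is cross-checked against an independent implementation of the same
moment method.

**Adaptive Benjamini–Hochberg.** Step-up adjusted p-values scaled by an
estimate of the proportion of true nulls. The default estimator is the
conservative mean-based $\hat\pi_0 = \min(1, 2\bar p)$; Storey's tail
estimator at $\lambda = 0.5$ (floored at $1/m$ so the procedure never
degenerates to rejecting everything) is selectable, and the estimator used
is recorded in the per-comparison metadata. At $\pi_0 = 1$ the adjustment is
exactly standard Benjamini–Hochberg.

**Merging and set composition.** Per protein, the merged volcano coordinates
are the signed maximum log2 fold change and the Fisher combination
$-2\sum \ln p_i \sim \chi^2_{2k}$ over whichever of the six comparisons
produced a value — missing comparisons are omitted, never zero-filled. The
enriched set is the union of the differential branch (significantly enriched
toward MBR+, adjusted p < `fdr_level`, in ≥ 1 comparison) and the absence
branch (present in MBR+, absent in ≥ `absent_rule_min_controls` distinct
control *fractions*; a protein absent versus the same fraction in both
preparations counts that fraction once). The default is one control
fraction; the stricter two-fraction variant is a config switch because both
rules appear in common use and neither is silently preferred — reports carry
the reasons for every inclusion. Per-protein counts of significant control
fractions (0–3) drive the volcano color classes.

**Cluster over-representation.** Hypergeometric upper-tail tests of each
functional cluster in a target list against the full MS-identified
background. Proteins with several cluster labels count in each; unannotated
proteins enlarge the background and target sizes only. No multiplicity
adjustment is applied across clusters — the 0.1 display cutoff carried in
the output is a reporting threshold, not an adjustment.

## The synthetic-data generator

`simulate_lfq()` emulates exactly the structure the analysis assumes:
baseline log2 abundances $N(25, 2^2)$ (a typical LFQ dynamic-range ballpark),
variances from the scaled inverse-chi-square prior with $d_0 = 4$ and
$s_0^2 = 0.04$ (a typical replicate residual sd of ≈ 0.2 log2 units, i.e.
~15–20% CV, with realistic protein-to-protein heterogeneity), 10% truly
enriched proteins with effects uniform on $[\log_2 1.3, 3]$ applied toward
MBR+ only (the evaluated set is directional), 5% of proteins entirely absent
outside MBR+, left-censored missingness with a logistic censor
(midpoint 20, slope 1 — low-abundance proteins lose observations first) plus
2% completely-at-random dropout. These defaults were fixed once as realistic
study conditions and are all exposed in `sim_params()`.

What the generator does **not** emulate: peptide-level assembly and razor
peptides, correlated variances across fractions, batch and run-order
effects, ratio compression, or interference between co-eluting proteins.
Passing tests on synthetic data therefore validate the decision procedure
under its own model assumptions, not the upstream quantification.

Simulation problem sizes used by the test suite and the calibration script —
up to m = 2000 proteins, 50 replicate datasets, and n = 5000 rows for moment
recovery checks — were chosen so that Monte-Carlo error is small relative to
the tolerances being checked.

## FDR behavior of the composed procedure

The package's calibration script (`scripts/acceptance.R`) measures the
false-discovery proportion of the differential branch against generator
truth. Three compounding effects make the *composed* procedure
anti-conservative even though its testing core is calibrated (per-comparison
FDP of the moderated test with adaptive BH on complete, ungated data is
below the nominal 5% in the package's own checks):

1. **Union over comparisons.** A protein false in any of the comparisons
   enters the enriched set, while true positives largely coincide across
   comparisons, so the union's FDP exceeds the per-comparison FDR.
2. **Missingness and single-draw imputation.** Left-censoring truncates
   observed intensities and a single conditional draw understates imputation
   uncertainty, both inflating |t| for proteins with many missing values.
3. **Gating before testing.** Selecting on $|\log_2\text{FC}| \ge \log_2 1.3$
   enriches the tested set for nulls that already have small p-values, and —
   when true effects dominate the gated set — collapses the mean-based
   $\hat\pi_0$ toward 0, making the adaptive adjustment nearly vacuous.

Under the generator's default conditions the measured mean differential-branch
FDP is far above the nominal 5% (≈ 35% in the calibration script's 50-dataset
run). Users who need calibrated error control should disable the gate
(`fc_threshold_raw` close to 1), prefer `pi0_method = "storey"` or π₀ = 1
behavior on heavily signal-dominated sets, and treat the gated-and-adjusted
output as a ranking rather than an error-controlled discovery list.

## Known limitations

- The normal EM imputation is deliberately mis-specified under the
  left-censored missingness the generator produces (and real LFQ data show):
  the pipeline reproduces the normal-model imputation tradition rather than
  a censored-likelihood model, and no multiple-imputation pooling is offered.
- Comparisons are two-group only; no covariates, pairing or variance trends.
- Identifier mapping between external lists and protein groups is the
  caller's responsibility (`overlap_with_list()` compares identifiers as
  given).
- GO terms are not resolved; cluster membership is consumed as a prebuilt
  two-column table.

## Reproducibility

Every stochastic step — simulation, conditional-draw imputation — derives a
31-bit stage seed from the single `seed` in `analysis_config()` /
`sim_params()`, so identical inputs and configuration give byte-identical
output files; the run manifest records the config digest, the seed and
per-step row counts, whose identities (filter chain non-increasing,
per-comparison statuses summing to the comparison input) are asserted by the
test suite.
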