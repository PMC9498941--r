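---
title: "Methods: probe-panel QC, signature scoring and concordance in oncopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-panel QC, signature scoring and concordance in oncopanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures implemented in
`oncopanel`, the assumptions behind them, the tunable parameters and their
defaults, and the design choices made where the published processing chain
for this class of assay leaves details open.

## The data and its processing model

A targeted probe-counting panel measures a few thousand transcripts on
hundreds-to-thousands of tissue-microarray cores. The raw output is an
integer count matrix (probes × samples) with two classes of internal
control: *negative-control probes* with no transcript target, whose signal
estimates non-specific background (incomplete digestion of non-hybridized
probes), and *housekeeping genes*, stably expressed transcripts used for
sample-quality calibration. Dedicated wells carry *universal RNA (uRNA)*
replicates — a fixed reference RNA whose average profile anchors a
correlation-based quality filter.

The processing chain, in fixed order:

1. **Sequencing-quality filter.** A sample is excluded when its total read
   count over all probes is below `min_total_reads` (default 1.5×10⁶ reads)
   or its relative standard deviation — the sample standard deviation of its
   probe counts divided by their mean — is below `min_rel_sd` (default 0.1).
   Both bounds are strict (< fails, = passes); a zero-total sample has
   undefined relative SD and fails. The relative-SD rule removes degenerate
   flat profiles (e.g. saturated or empty wells).
2. **Background subtraction.** Per sample, the background is the arithmetic
   mean of that sample's negative-control counts, subtracted from every gene
   probe with clamping at zero. The mean (rather than a quantile or maximum)
   is the minimal-assumption estimator of a probe-independent noise floor,
   and clamping preserves count semantics.
3. **adjCPM.** Each sample is scaled to 10⁶ over gene probes. A sample with
   a zero post-subtraction total is a hard error: such a sample should
   already have failed QC.
4. **Upper-quartile normalization.** Each sample is divided by the
   `uq_quantile` (default 0.75) quantile of its strictly positive values and
   rescaled by the median of those per-sample quartiles. Computing the
   quantile over positive values only keeps the statistic independent of the
   panel's zero mass; rescaling by the cohort median preserves the overall
   scale so that log values remain comparable across reruns and cohorts.
   Quantiles use R's default type 7 definition.
5. **Log transform.** `log2(x + 1)` elementwise; zeros map to zero.
6. **Sample-quality filter.** Each sample's log-expression vector is
   correlated (Pearson by default; Spearman switchable) with the mean uRNA
   profile computed from the uRNA replicates that passed the sequencing
   filter. Samples with R < `min_urna_corr` (default 0.4) are labelled
   low-quality. The *exclusion parameter* is then calibrated empirically: the
   mean log expression of the `n_housekeeping_required` (default 9)
   housekeeping genes is thresholded at the cut that minimizes
   misclassification of the low-quality labels — a 1-D decision stump over
   all midpoints between consecutive sorted housekeeping means (plus the
   smallest observed value, so that a cohort with no low-quality samples
   excludes nobody). Ties resolve toward the smallest threshold. The final
   pass flag is `seq_pass AND housekeeping_mean >= threshold`; whether the
   R < 0.4 label should *also* gate the final set is genuinely ambiguous in
   the published description, so both flags are reported and
   `qc_config(final_rule = "stump_and_corr")` switches to the joint rule.

Throughout the package the standard deviation is the sample SD (n − 1).

## Z-scores, signatures and subtype assignment

Z-scores standardize each gene over a declared *universe* of samples; by
convention the universe is all tumor + normal samples passing QC for
signature analyses, and all tumor samples for amplicon calling (both
configurable). Samples outside the universe are standardized with the
universe's mean and SD, so reference cohorts can anchor the scale. Genes
constant over the universe are given all-zero rows and flagged rather than
dropped, keeping signature gene counts stable.

A signature is a named set of `high` and `low` marker genes. Its score for
sample *s* is the signed mean `mean_g(σ_g z[g, s])` with σ = +1 for high and
−1 for low genes. Where both directions exist, the signed average (rather
than a high-only mean) uses all the discriminating information; this choice
is documented because published descriptions often leave it implicit. The
molecular subtype of a sample is the argmax over its subtype scores; exact
ties break lexicographically by subtype name and are flagged, and the margin
(best − second) is reported so weak calls can be identified downstream —
`reannotate()` flags margins below `weak_margin` (default 0.1 z-units).

Marker selection tests each gene, target group versus comparator, with a
two-sided Welch t-test on log2 values (Wilcoxon switchable; the published
thresholds never name their test, and Welch on log2 values is the field's
default). Genes pass at raw `p < p_threshold` (e.g. 0.005 within a cancer
type, 0.05 for a coarser contrast) with an optional absolute
log2-fold-change floor; *no multiple-testing correction* is applied, matching
the raw-threshold convention of this analysis style. The Welch statistic is
computed vectorised over genes with the Welch–Satterthwaite degrees of
freedom and is cross-checked against `stats::t.test` in the unit tests.

## Expression-amplicon calling

`find_neighbors()` returns the genes whose interval overlaps the half-open
window `[anchor_start − w, anchor_end + w)` on the anchor's chromosome, with
`w = 51000` bp by default — for ERBB2/HER2 this yields the anchor plus its
seven neighbors. Coordinates are BED-convention 0-based half-open and strand
is ignored (the window is symmetric). The window is measured from the
anchor's interval ends, not its midpoint, and any overlap suffices for
inclusion. A sample is amplicon-positive when its mean z over the
neighborhood strictly exceeds `z_threshold` (default 1.5). The anchor is
included in the mean by default (`include_anchor` switches this off; the
published rule does not say whether the anchor participates in its own
average, and including it is the natural reading of "the amplicon").

## mRNA–protein and cross-platform concordance

`platform_concordance()` reports, per shared gene, the Pearson correlation
and the OLS slope/intercept of platform 2 on platform 1 across shared
samples, after removing an optional probe blacklist (panels exclude a
handful of probes from cross-build comparisons; the list is user-supplied,
never hard-coded). Slopes outside `1 ± slope_delta` (default 0.25) are
flagged as platform bias (`low_in_p2` / `high_in_p2`).

`mrna_protein_by_group()` correlates log2 expression with the
immunohistochemistry H-score (0–300) within each sample group; correlations
are Pearson on log2 expression versus raw H-score, matching the linear-scale
scatter convention for these data (Spearman switchable). IHC positivity is
the percentage of samples graded 2+ or 3+. When a metadata table carries
H-scores but no grades, `hscore_to_ihc()` bins at <1 / ≤100 / ≤200 / >200;
the bins are configurable and are a package convention, since H-scores and
grades are usually reported as parallel readouts without a stated mapping.

Narrative discordance ("expresses the mRNA but almost no protein") is
formalized as a percentile-rank gap: each group's median mRNA and median
H-score are ranked across groups on [0, 1], and a gap above `rank_gap`
(default 0.3) in either direction raises `high_mrna_low_protein` or
`low_mrna_high_protein`. Rank gaps are only meaningful when group medians
genuinely differ; with near-identical medians the ranks, and hence the
flags, are noise-driven, which is why the flags accompany — never replace —
the underlying medians and correlations in the report.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts with the statistical structure the chain
assumes, plus planted ground truth for recovery tests:

* **Counts** are gamma-Poisson: gene g in sample s has mean
  `f_s · μ_g · 2^(marker + amplicon effects)` with dispersion shared across
  genes (default 0.1; targeted probe panels are precise, and variance
  `μ + 0.1 μ²` matches a mid-precision bulk assay), plus Poisson background
  with mean `background_mean` (default 30 counts) added to *every* probe.
  Negative-control probes carry background only. Baselines μ are lognormal
  (log-mean log 150, log-SD 1.2) for a realistic panel dynamic range;
  housekeeping genes are high and tight (log-mean log 1500, log-SD 0.15)
  with no group effects by construction.
* **Depth** is Gaussian with mean 3×10⁶ reads and CV 0.1, truncated below at
  10% of the mean. The CV is deliberately modest: the planted-recovery
  properties ("exactly the planted failures are excluded") presuppose that
  organic depth failures essentially never occur, which holds when the
  1.5×10⁶ filter sits several SDs below the mean.
* **Planted failures**: read-count failures have their depth set to
  min(0.3 × mean, 10⁶) reads; low-quality samples have their gene counts
  permuted within-sample and housekeeping counts multiplied by 0.2, which
  defeats both the uRNA correlation filter and the housekeeping stump it
  calibrates.
* **uRNA replicates** are independent draws around the baseline profile μ.
* **Amplicon carriers** are Bernoulli(`amplicon_prevalence`, default 0.1)
  among tumor samples; carriers multiply the 8 amplicon genes (anchor + 7
  neighbors, laid out inside a ±51 kb window on chr17 in the emitted BED) by
  `2^amplicon_log2fc` (default log2FC 2).
* **H-scores** for tracked genes follow `H = 300·L/(L + K) + ε`, clipped to
  [0, 300] and reported at one-decimal precision, where the latent protein
  `L` is the sample's realized depth-normalized transcript level times a
  per-group attenuation factor (1 = faithful, 0 = fully decoupled protein),
  `K` is the cohort-median latent (so the median sample scores ≈ 150), and
  ε is Gaussian with SD `hscore_noise_sd` (default 15 H-units). Latent
  protein tracks the *realized* counts rather than the group mean so that
  within-group mRNA–protein correlation exists and degrades smoothly with
  attenuation. Because K sits at the cohort median, the saturating map is
  steepest there: attenuation sweeps are monotone in r when one decoupled
  group is swept against an otherwise faithful cohort (the regime the
  recovery tests use), not when the whole cohort is attenuated at once.

The generator emulates library-size variation, background, stable
housekeeping signal, control replicates, subtype markers, a co-amplified
neighborhood, and expression-coupled H-scores. It does **not** emulate
probe-level GC or sequence bias, FFPE degradation chemistry, isoform
structure, batch effects, or correlated gene modules beyond the planted
structure — so passing recovery tests demonstrate the correctness of the
statistical machinery under the stated model, not robustness to every
artifact of clinical data.

## Numerical conventions and degenerate inputs

* Quantiles: `stats::quantile` type 7; positive values only for UQ.
* SD: sample convention (n − 1) everywhere.
* Strict inequalities: QC bounds fail at `<`, pass at `=`; amplicon calls
  require mean z strictly `>` threshold (a neighborhood sitting exactly at
  1.5 is never called).
* Stump ties resolve to the smallest threshold; argmax ties resolve
  lexicographically and are flagged.
* Degenerate genes z-score to 0 and are flagged; constant readouts yield
  `NA` correlations rather than errors; samples with zero totals or no
  positive values are hard errors naming the sample.
* All readers validate and never silently drop rows; record counts are
  logged. Reader/writer pairs round-trip valid files exactly (H-scores are
  generated at fixed decimal precision so text round-trips are bitwise).

## Problem sizes in the test-suite

The suite exercises the chain at desk scale, chosen to keep the full run
fast while leaving comfortable statistical margins: QC recovery on a
200-sample, 500-gene cohort with 5 + 5 planted failures; normalization
oracles on 500 × 50 matrices at 10⁻⁹ tolerance; marker-selection null
calibration at 2,000 genes × 20 replicates against the exact binomial 99%
interval; subtype recovery at 4 × 50 samples with 30 markers per group;
amplicon recovery on 500 samples at 10% prevalence; and concordance recovery
on 8 × 25-sample groups with one fully decoupled group.

## Known limitations

* The housekeeping stump is calibrated against the R < 0.4 labels of the
  same cohort; with very few low-quality samples the threshold is driven by
  a handful of points, as any empirical exclusion parameter is.
* Welch t at raw thresholds controls no family-wise error; marker lists are
  meant as signature inputs, not as inference about individual genes.
* Rank-gap discordance flags are undefined under near-identical group
  medians (see above) and require at least 3 groups.
* The generator's shared-dispersion NB model understates gene-specific
  dispersion heterogeneity of real panels.
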