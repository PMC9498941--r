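#' QC and normalization thresholds
#'
#' Defaults follow the published processing of the assay: samples with fewer
#' than 1.5 million total reads or a relative standard deviation (sd/mean
#' across probes) below 0.1 are excluded; samples whose log-expression
#' correlates with the mean uRNA reference at R < 0.4 are labelled low
#' quality; the final exclusion threshold is calibrated on the mean
#' log-expression of nine housekeeping genes.
#'
#' @param min_total_reads Minimum per-sample total read count (strict: equal
#'   passes).
#' @param min_rel_sd Minimum per-sample relative standard deviation of probe
#'   counts (strict).
#' @param min_urna_corr Correlation threshold against the uRNA reference
#'   below which a sample is labelled low quality.
#' @param n_housekeeping_required Number of housekeeping genes the
#'   sample-quality filter expects.
#' @param uq_quantile Quantile used by upper-quartile normalization.
#' @param correlation_method `"pearson"` (default) or `"spearman"` for the
#'   uRNA correlation.
#' @param final_rule `"stump"` (default): `final_pass = seq_pass &
#'   housekeeping_mean >= threshold`; `"stump_and_corr"` additionally
#'   requires the correlation flag itself to pass.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_total_reads = 1.5e6,
                      min_rel_sd = 0.1,
                      min_urna_corr = 0.4,
                      n_housekeeping_required = 9,
                      uq_quantile = 0.75,
                      correlation_method = c("pearson", "spearman"),
                      final_rule = c("stump", "stump_and_corr")) {
  stopifnot(min_total_reads > 0, min_rel_sd >= 0,
            min_urna_corr >= -1, min_urna_corr <= 1,
            n_housekeeping_required >= 1,
            uq_quantile > 0, uq_quantile < 1)
  structure(list(
    min_total_reads = min_total_reads,
    min_rel_sd = min_rel_sd,
    min_urna_corr = min_urna_corr,
    n_housekeeping_required = as.integer(n_housekeeping_required),
    uq_quantile = uq_quantile,
    correlation_method = match.arg(correlation_method),
    final_rule = match.arg(final_rule)
  ), class = "qc_config")
}

#' Sequencing-quality filter
#'
#' Excludes samples whose total read count (sum over all probes, controls
#' included) falls below `min_total_reads`, or whose relative standard
#' deviation (sample sd / mean of the probe counts) falls below
#' `min_rel_sd`. Bounds are strict: a value exactly at the threshold passes.
#' A zero-total sample has undefined relative SD and fails.
#'
#' @param counts Probe count tibble ([read_counts()] layout).
#' @param cfg A [qc_config()].
#' @return List with `counts` (the kept samples) and `report` (one row per
#'   input sample: `sample_id`, `total_reads`, `rel_sd`, `seq_pass`).
#' @export
sequencing_quality_filter <- function(counts, cfg = qc_config()) {
  validate_counts(counts)
  m <- tbl_to_matrix(counts[, -(2:3)])
  totals <- colSums(m)
  rel_sd <- apply(m, 2, function(x) if (mean(x) == 0) NA_real_ else sample_sd(x) / mean(x))
  seq_pass <- totals >= cfg$min_total_reads & !is.na(rel_sd) & rel_sd >= cfg$min_rel_sd
  report <- tibble::tibble(
    sample_id = colnames(m),
    total_reads = unname(totals),
    rel_sd = unname(rel_sd),
    seq_pass = unname(seq_pass)
  )
  kept <- dplyr::bind_cols(counts[1:3], counts[, colnames(m)[seq_pass], drop = FALSE])
  list(counts = kept, report = report)
}

#' Subtract negative-control background
#'
#' Per sample, the background is the arithmetic mean of that sample's
#' negative-control probe counts; it is subtracted from every gene probe and
#' the result clamped at zero. Control rows are dropped from the output.
#'
#' @param counts Probe count tibble with at least one `neg_ctrl` probe.
#' @return Tibble `gene_id` + one numeric column per sample.
#' @export
subtract_background <- function(counts) {
  is_neg <- counts$probe_class == "neg_ctrl"
  if (!any(is_neg)) config_error("no negative-control probes: background cannot be estimated")
  if (!any(!is_neg)) config_error("no gene probes present")
  m <- tbl_to_matrix(counts[, -(2:3)])
  bg <- colMeans(m[is_neg, , drop = FALSE])
  adj <- pmax(sweep(m[!is_neg, , drop = FALSE], 2, bg, `-`), 0)
  matrix_to_tbl(adj, "gene_id")
}

#' Scale samples to adjusted counts per million
#'
#' Each sample's background-adjusted values are scaled to sum to 1e6 over
#' the gene probes.
#'
#' @param adjusted Tibble `gene_id` + numeric sample columns (output of
#'   [subtract_background()]).
#' @return adjCPM tibble of the same shape.
#' @export
adjcpm <- function(adjusted) {
  assert_expr_tbl(adjusted, "adjusted")
  m <- tbl_to_matrix(adjusted)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    config_error(sprintf(
      "sample(s) with zero post-subtraction total: %s (should have failed QC)",
      paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  matrix_to_tbl(sweep(m, 2, 1e6 / totals, `*`), "gene_id")
}

#' Upper-quartile normalization
#'
#' Per sample, values are divided by the `uq_quantile` quantile of that
#' sample's strictly positive values and rescaled by the median of those
#' per-sample quantiles, so the overall scale is preserved.
#'
#' @param cpm adjCPM tibble (output of [adjcpm()]).
#' @param cfg A [qc_config()] (supplies `uq_quantile`).
#' @return adjCPM-UQ tibble.
#' @export
uq_normalize <- function(cpm, cfg = qc_config()) {
  assert_expr_tbl(cpm, "cpm")
  m <- tbl_to_matrix(cpm)
  uq <- apply(m, 2, function(x) {
    pos <- x[x > 0]
    if (!length(pos)) NA_real_ else unname(quantile(pos, cfg$uq_quantile, type = 7))
  })
  if (anyNA(uq)) {
    config_error(sprintf("sample(s) with no positive values: %s",
                         paste(colnames(m)[is.na(uq)], collapse = ", ")))
  }
  matrix_to_tbl(sweep(m, 2, median(uq) / uq, `*`), "gene_id")
}

#' Log-transform normalized expression
#'
#' Elementwise `log2(x + 1)`; zeros map to zero. Negative input violates the
#' pipeline's invariants and raises an error.
#'
#' @param uq adjCPM-UQ tibble.
#' @return Expression tibble (`gene_id` + log2 sample columns).
#' @export
log_transform <- function(uq) {
  assert_expr_tbl(uq, "uq")
  m <- tbl_to_matrix(uq)
  if (any(m < 0)) onco_abort("negative values passed to log_transform()", "oncopanel_invariant_error")
  matrix_to_tbl(log2(m + 1), "gene_id")
}

#' Mean uRNA reference profile
#'
#' Arithmetic mean per gene over the universal-RNA control replicates
#' present in the expression table (i.e. those that passed the sequencing
#' filter).
#'
#' @param expr Expression tibble.
#' @param samples Sample metadata tibble.
#' @return Tibble `gene_id`, `reference`.
#' @export
urna_reference <- function(expr, samples) {
  assert_expr_tbl(expr)
  ur <- samples$sample_id[samples$sample_role == "urna_control"]
  ur <- intersect(ur, sample_cols(expr, "gene_id"))
  if (length(ur) < 2) {
    config_error(sprintf("need >=2 uRNA control samples for a reference, found %d", length(ur)))
  }
  m <- tbl_to_matrix(expr[, c("gene_id", ur)])
  tibble::tibble(gene_id = rownames(m), reference = unname(rowMeans(m)))
}

#' Sample-quality filter
#'
#' Correlates each sample's log-expression with the uRNA reference profile;
#' samples below `min_urna_corr` are labelled low quality. The exclusion
#' parameter is then calibrated empirically: the mean log expression of the
#' housekeeping genes is thresholded at the midpoint cut (1-D decision
#' stump) that minimizes misclassification of the low-quality labels, ties
#' resolved toward the smallest threshold. `final_pass` requires the
#' housekeeping mean to reach the threshold.
#'
#' @param expr Expression tibble (sequencing-filter survivors).
#' @param reference Output of [urna_reference()].
#' @param housekeeping_genes Character vector of housekeeping gene ids;
#'   length must equal `cfg$n_housekeeping_required`.
#' @param cfg A [qc_config()].
#' @return A `qc_report` tibble (`sample_id`, `urna_corr`,
#'   `housekeeping_mean`, `quality_pass`, `final_pass`) with the calibrated
#'   threshold in attribute `housekeeping_threshold`.
#' @export
sample_quality_filter <- function(expr, reference, housekeeping_genes, cfg = qc_config()) {
  assert_expr_tbl(expr)
  if (length(housekeeping_genes) != cfg$n_housekeeping_required) {
    config_error(sprintf("expected %d housekeeping genes, got %d",
                         cfg$n_housekeeping_required, length(housekeeping_genes)))
  }
  m <- tbl_to_matrix(expr)
  if (!all(housekeeping_genes %in% rownames(m))) {
    config_error("housekeeping gene(s) missing from the expression table")
  }
  ref <- reference$reference[match(rownames(m), reference$gene_id)]
  if (anyNA(ref)) config_error("reference profile does not cover all genes")
  urna_corr <- apply(m, 2, function(x) cor(x, ref, method = cfg$correlation_method))
  low_quality <- urna_corr < cfg$min_urna_corr
  hk_mean <- colMeans(m[housekeeping_genes, , drop = FALSE])
  t_star <- stump_threshold(hk_mean, low_quality)
  final <- hk_mean >= t_star
  if (cfg$final_rule == "stump_and_corr") final <- final & !low_quality
  report <- tibble::tibble(
    sample_id = colnames(m),
    urna_corr = unname(urna_corr),
    housekeeping_mean = unname(hk_mean),
    quality_pass = unname(!low_quality),
    final_pass = unname(final)
  )
  attr(report, "housekeeping_threshold") <- t_star
  class(report) <- c("qc_report", class(report))
  report
}

# Optimal 1-D decision stump: predict "fail" when x < t. Candidates are the
# smallest observed value (nothing excluded) and all midpoints between
# consecutive sorted unique values; ties go to the smallest threshold.
stump_threshold <- function(x, fail_label) {
  ux <- sort(unique(x))
  cand <- c(ux[1], if (length(ux) > 1) (ux[-1] + ux[-length(ux)]) / 2)
  errs <- vapply(cand, function(t) sum(fail_label & x >= t) + sum(!fail_label & x < t), numeric(1))
  cand[which.min(errs)]
}

#' Run the full QC and normalization chain
#'
#' Sequencing filter, background subtraction, adjCPM, upper-quartile
#' normalization, log2 transform, uRNA reference and sample-quality filter,
#' in the fixed published order. The returned report has one row per input
#' sample; samples removed by the sequencing filter carry NA quality fields
#' and `final_pass = FALSE`.
#'
#' @param counts Probe count tibble.
#' @param samples Sample metadata tibble.
#' @param cfg A [qc_config()].
#' @return List with `report` (full `qc_report`), `expr` (expression tibble
#'   for all sequencing-filter survivors), `expr_pass` (final-pass samples
#'   only), `reference`, and `housekeeping_threshold`.
#' @export
run_qc <- function(counts, samples, cfg = qc_config()) {
  seq_stage <- sequencing_quality_filter(counts, cfg)
  hk_genes <- counts$probe_id[counts$housekeeping]
  expr <- seq_stage$counts |>
    subtract_background() |>
    adjcpm() |>
    uq_normalize(cfg) |>
    log_transform()
  ref <- urna_reference(expr, samples)
  qual <- sample_quality_filter(expr, ref, hk_genes, cfg)
  report <- dplyr::left_join(seq_stage$report, qual, by = "sample_id")
  report$final_pass <- report$seq_pass & !is.na(report$final_pass) & report$final_pass
  attr(report, "housekeeping_threshold") <- attr(qual, "housekeeping_threshold")
  class(report) <- c("qc_report", class(report))
  keep <- report$sample_id[report$final_pass]
  list(
    report = report,
    expr = expr,
    expr_pass = expr[, c("gene_id", intersect(sample_cols(expr, "gene_id"), keep))],
    reference = ref,
    housekeeping_threshold = attr(qual, "housekeeping_threshold")
  )
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_seq_fail = if ("seq_pass" %in% names(x)) sum(!x$seq_pass) else NA_integer_,
    n_low_quality = sum(!x$quality_pass, na.rm = TRUE),
    n_final_pass = sum(x$final_pass, na.rm = TRUE),
    housekeeping_threshold = attr(x, "housekeeping_threshold") %||% NA_real_
  )
}
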