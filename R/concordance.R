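#' Per-gene cross-platform concordance
#'
#' For every gene shared by two expression tables (minus an optional
#' blacklist of excluded probes), computes the Pearson correlation and the
#' ordinary least-squares slope/intercept of platform 2 (`y`) on platform 1
#' (`x`) across the shared samples. Slopes far from 1 are flagged as
#' platform bias: `low_in_p2` when `slope < 1 - slope_delta`, `high_in_p2`
#' when `slope > 1 + slope_delta`.
#'
#' @param x,y Expression tibbles (`gene_id` + sample columns) for the two
#'   platforms.
#' @param blacklist Optional character vector of genes to exclude before
#'   comparison.
#' @param slope_delta Half-width of the "no bias" slope band around 1.
#' @return A `platform_concordance` tibble: `gene_id`, `r`, `slope`,
#'   `intercept`, `n`, `bias_flag`.
#' @export
platform_concordance <- function(x, y, blacklist = NULL, slope_delta = 0.25) {
  assert_expr_tbl(x, "x"); assert_expr_tbl(y, "y")
  genes <- setdiff(intersect(x$gene_id, y$gene_id), blacklist)
  if (!length(genes)) config_error("no shared genes after applying the blacklist")
  shared <- intersect(sample_cols(x, "gene_id"), sample_cols(y, "gene_id"))
  if (length(shared) < 3) {
    config_error(sprintf("need >= 3 shared samples, found %d", length(shared)))
  }
  mx <- tbl_to_matrix(x[match(genes, x$gene_id), c("gene_id", shared)])
  my <- tbl_to_matrix(y[match(genes, y$gene_id), c("gene_id", shared)])
  n <- length(shared)
  xb <- rowMeans(mx); yb <- rowMeans(my)
  sxx <- rowSums((mx - xb)^2)
  sxy <- rowSums((mx - xb) * (my - yb))
  syy <- rowSums((my - yb)^2)
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  out <- tibble::tibble(
    gene_id = genes,
    r = unname(r),
    slope = unname(slope),
    intercept = unname(yb - slope * xb),
    n = n,
    bias_flag = dplyr::case_when(
      is.na(slope) ~ NA_character_,
      slope < 1 - slope_delta ~ "low_in_p2",
      slope > 1 + slope_delta ~ "high_in_p2",
      .default = "none"
    )
  )
  class(out) <- c("platform_concordance", class(out))
  out
}

#' Group-level mRNA-protein agreement
#'
#' For each sample group carrying H-scores for `gene` (at least `min_n`
#' samples with both readouts), reports the median log2 expression, median
#' H-score and the within-group correlation of the two; the pooled
#' all-sample correlation is stored in attribute `pooled_r`. Groups with a
#' degenerate (constant) readout report `r_mrna_protein = NA`.
#'
#' @param expr Expression tibble.
#' @param samples Sample metadata with an `hscore_<gene>` column.
#' @param gene Gene id to analyse.
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param min_n Minimum samples per reported group.
#' @return A `group_protein` tibble: `group`, `n`, `median_mrna`,
#'   `median_hscore`, `r_mrna_protein`.
#' @export
mrna_protein_by_group <- function(expr, samples, gene,
                                  method = c("pearson", "spearman"), min_n = 3) {
  assert_expr_tbl(expr)
  method <- match.arg(method)
  if (!gene %in% expr$gene_id) config_error(sprintf("gene '%s' absent from the expression table", gene))
  hcol <- paste0("hscore_", gene)
  if (!hcol %in% names(samples)) {
    config_error(sprintf("metadata has no H-score column '%s'", hcol))
  }
  ev <- unlist(expr[expr$gene_id == gene, sample_cols(expr, "gene_id")])
  d <- tibble::tibble(
    sample_id = names(ev),
    mrna = unname(ev)
  ) |>
    dplyr::inner_join(
      dplyr::select(samples, "sample_id", "group", hscore = dplyr::all_of(hcol)),
      by = "sample_id"
    ) |>
    dplyr::filter(!is.na(.data$hscore))
  if (!nrow(d)) config_error(sprintf("no samples with H-scores for '%s'", gene))
  skipped <- d |> dplyr::count(.data$group) |> dplyr::filter(.data$n < min_n)
  if (nrow(skipped)) {
    inform(sprintf("skipping group(s) with < %d scored samples: %s", min_n,
                   paste(skipped$group, collapse = ", ")))
  }
  out <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(dplyr::n() >= min_n) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_mrna = median(.data$mrna),
      median_hscore = median(.data$hscore),
      r_mrna_protein = safe_cor(.data$mrna, .data$hscore, method),
      .groups = "drop"
    )
  if (!nrow(out)) config_error(sprintf("no group has >= %d H-scored samples for '%s'", min_n, gene))
  attr(out, "pooled_r") <- safe_cor(d$mrna, d$hscore, method)
  attr(out, "gene") <- gene
  class(out) <- c("group_protein", class(out))
  out
}

# correlation that returns NA (rather than erroring/warning) when a vector
# is constant
safe_cor <- function(x, y, method = "pearson") {
  if (sample_sd(x) == 0 || sample_sd(y) == 0 || length(x) < 3) return(NA_real_)
  cor(x, y, method = method)
}

#' Per-group IHC positivity
#'
#' Positivity is the percentage of samples with IHC category 2+ or 3+ (the
#' published positivity rule); groups are returned sorted by descending
#' positivity.
#'
#' @param samples Sample metadata with an `ihc_<gene>` column.
#' @param gene Gene id.
#' @return Tibble `group`, `n`, `pct_ihc_positive`, sorted descending.
#' @export
ihc_positivity <- function(samples, gene) {
  icol <- paste0("ihc_", gene)
  if (!icol %in% names(samples)) {
    config_error(sprintf("metadata has no IHC column '%s'", icol))
  }
  d <- samples |>
    dplyr::select("sample_id", "group", ihc = dplyr::all_of(icol)) |>
    dplyr::filter(!is.na(.data$ihc))
  if (!nrow(d)) config_error(sprintf("no IHC category data for '%s'", gene))
  d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_ihc_positive = 100 * mean(.data$ihc %in% c(2L, 3L)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$pct_ihc_positive))
}

#' Flag mRNA-protein discordant groups
#'
#' Formalizes narrative discordance ("expresses the mRNA but almost no
#' protein") as a percentile-rank gap: each group's median mRNA and median
#' H-score are converted to percentile ranks across groups, and a group is
#' flagged `high_mrna_low_protein` when `rank_mrna - rank_protein >
#' rank_gap` (default 0.3), conversely `low_mrna_high_protein`.
#'
#' @param rows A `group_protein` tibble from [mrna_protein_by_group()]
#'   (needs >= 3 groups).
#' @param rank_gap Rank-gap threshold in `[0, 1]`.
#' @return The input with `rank_mrna`, `rank_protein` and `discordance`
#'   columns added.
#' @export
discordance_flags <- function(rows, rank_gap = 0.3) {
  if (nrow(rows) < 3) config_error("need >= 3 groups to assess discordance")
  rows$rank_mrna <- pct_rank(rows$median_mrna)
  rows$rank_protein <- pct_rank(rows$median_hscore)
  gap <- rows$rank_mrna - rows$rank_protein
  rows$discordance <- dplyr::case_when(
    gap > rank_gap ~ "high_mrna_low_protein",
    gap < -rank_gap ~ "low_mrna_high_protein",
    .default = "none"
  )
  rows
}
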