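#' Per-gene Z-scores over a declared sample universe
#'
#' Standardizes each gene to mean 0, sample SD 1 (n-1 denominator) computed
#' over the `universe` samples; samples outside the universe are
#' standardized with the universe's mean and SD. Genes that are constant
#' over the universe get an all-zero row and are flagged as degenerate, so
#' signature gene counts stay stable.
#'
#' @param expr Expression tibble (`gene_id` + numeric sample columns).
#' @param universe Character vector of sample ids (>= 2) defining the
#'   standardization universe; defaults to all samples.
#' @return A z-score tibble of the same shape, with attributes `universe`
#'   and `degenerate_genes`.
#' @export
zscore <- function(expr, universe = NULL) {
  assert_expr_tbl(expr)
  smp <- sample_cols(expr, "gene_id")
  universe <- universe %||% smp
  if (!all(universe %in% smp)) {
    config_error("z-score universe contains samples absent from the expression table")
  }
  if (length(universe) < 2) config_error("z-score universe must contain >= 2 samples")
  m <- tbl_to_matrix(expr)
  u <- m[, universe, drop = FALSE]
  mu <- rowMeans(u)
  sdv <- apply(u, 1, sample_sd)
  degenerate <- sdv == 0 | is.na(sdv)
  sdv[degenerate] <- 1
  z <- (m - mu) / sdv
  z[degenerate, ] <- 0
  out <- matrix_to_tbl(z, "gene_id")
  attr(out, "universe") <- universe
  attr(out, "degenerate_genes") <- rownames(m)[degenerate]
  out
}

#' Score samples against a signed signature
#'
#' The score of sample `s` is the mean over the signature's genes of
#' `+z[g, s]` for high genes and `-z[g, s]` for low genes. Signature genes
#' absent from the z-table are reported and skipped; a signature with no
#' overlapping genes is an error.
#'
#' @param z Z-score tibble from [zscore()].
#' @param sig A [signature_set()].
#' @return Tibble `sample_id`, `score`.
#' @export
signature_score <- function(z, sig) {
  assert_expr_tbl(z, "z")
  genes <- c(sig$high, sig$low)
  signs <- c(rep(1, length(sig$high)), rep(-1, length(sig$low)))
  present <- genes %in% z$gene_id
  if (!any(present)) {
    config_error(sprintf("signature '%s' shares no genes with the z-score table", sig$subtype))
  }
  if (any(!present)) {
    inform(sprintf("signature '%s': skipping %d absent gene(s): %s", sig$subtype,
                   sum(!present), paste(genes[!present], collapse = ", ")))
  }
  m <- tbl_to_matrix(z)
  zz <- m[genes[present], , drop = FALSE] * signs[present]
  tibble::tibble(sample_id = colnames(m), score = unname(colMeans(zz)))
}

#' Select subtype marker genes by differential expression
#'
#' Two-sided per-gene test (Welch t by default) of the target group against
#' a comparator (the other tumor groups, optionally plus normal samples) on
#' log2 expression values. Genes with raw `p < p_threshold` and
#' `|mean difference| >= min_abs_log2fc` are selected; the sign of the mean
#' difference assigns the `high`/`low` direction. No multiple-testing
#' correction is applied — the raw-threshold convention of the analysis this
#' package implements.
#'
#' @param expr Expression tibble.
#' @param samples Sample metadata tibble.
#' @param target_group Group to discriminate.
#' @param p_threshold Raw p-value threshold (e.g. 0.005 or 0.05).
#' @param comparator `"other_subtypes"` (other tumor groups) or
#'   `"other_subtypes_plus_normal"`.
#' @param min_abs_log2fc Minimum absolute mean log2 difference.
#' @param test `"welch_t"` (default) or `"wilcoxon"`.
#' @return A `marker_fit` object; see [tidy.marker_fit()],
#'   [glance.marker_fit()] and [as_signature_set()].
#' @export
select_markers <- function(expr, samples, target_group,
                           p_threshold = 0.005,
                           comparator = c("other_subtypes", "other_subtypes_plus_normal"),
                           min_abs_log2fc = 0,
                           test = c("welch_t", "wilcoxon")) {
  assert_expr_tbl(expr)
  comparator <- match.arg(comparator)
  test <- match.arg(test)
  stopifnot(p_threshold > 0, p_threshold < 1, min_abs_log2fc >= 0)
  smp <- sample_cols(expr, "gene_id")
  tumor <- samples$sample_id[samples$sample_role == "tumor"]
  target <- intersect(samples$sample_id[samples$group == target_group], smp)
  comp_groups <- samples$sample_role == "tumor" & samples$group != target_group
  if (comparator == "other_subtypes_plus_normal") {
    comp_groups <- comp_groups | samples$sample_role == "normal"
  }
  comp <- intersect(samples$sample_id[comp_groups], smp)
  if (length(target) < 3) config_error(sprintf("target group '%s' has %d samples; need >= 3",
                                               target_group, length(target)))
  if (length(comp) < 3) config_error("comparator has fewer than 3 samples")
  m <- tbl_to_matrix(expr)
  x <- m[, target, drop = FALSE]
  y <- m[, comp, drop = FALSE]
  stats <- if (test == "welch_t") welch_rows(x, y) else wilcox_rows(x, y)
  stats <- dplyr::mutate(
    stats,
    gene_id = rownames(m),
    log2fc = rowMeans(x) - rowMeans(y),
    .before = 1
  )
  stats$selected <- !is.na(stats$p_value) & stats$p_value < p_threshold &
    abs(stats$log2fc) >= min_abs_log2fc
  stats$direction <- ifelse(stats$log2fc > 0, "high", "low")
  structure(list(
    stats = stats,
    target_group = target_group,
    comparator = comparator,
    test = test,
    p_threshold = p_threshold,
    min_abs_log2fc = min_abs_log2fc,
    n_target = length(target),
    n_comparator = length(comp)
  ), class = "marker_fit")
}

# Vectorized two-sided Welch t-test over matrix rows (x vs y), with the
# Welch-Satterthwaite degrees of freedom; agrees with stats::t.test.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(stat), df)
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

wilcox_rows <- function(x, y) {
  res <- purrr::map(seq_len(nrow(x)), function(i) {
    w <- suppressWarnings(wilcox.test(x[i, ], y[i, ], exact = FALSE))
    c(w$statistic, w$p.value)
  })
  tibble::tibble(
    statistic = purrr::map_dbl(res, 1),
    df = NA_real_,
    p_value = purrr::map_dbl(res, 2)
  )
}

#' @describeIn select_markers Per-gene test statistics as a tibble.
#' @param x A `marker_fit`.
#' @param ... Unused.
#' @export
tidy.marker_fit <- function(x, ...) x$stats

#' @describeIn select_markers One-row model summary.
#' @export
glance.marker_fit <- function(x, ...) {
  tibble::tibble(
    target_group = x$target_group,
    test = x$test,
    p_threshold = x$p_threshold,
    n_target = x$n_target,
    n_comparator = x$n_comparator,
    n_selected = sum(x$stats$selected),
    n_high = sum(x$stats$selected & x$stats$direction == "high"),
    n_low = sum(x$stats$selected & x$stats$direction == "low")
  )
}

#' Convert a marker fit into a signed signature
#'
#' @param fit A `marker_fit` from [select_markers()].
#' @param subtype Signature name (defaults to the fit's target group).
#' @return A [signature_set()].
#' @export
as_signature_set <- function(fit, subtype = fit$target_group) {
  sel <- fit$stats[fit$stats$selected, ]
  if (!nrow(sel)) config_error(sprintf("no markers selected for '%s'", subtype))
  signature_set(subtype,
                high = sel$gene_id[sel$direction == "high"],
                low = sel$gene_id[sel$direction == "low"])
}

#' Assign molecular subtypes by maximum signature score
#'
#' Scores every sample against every signature and assigns the subtype with
#' the maximum score. Exact ties are broken lexicographically by subtype
#' name and flagged. The margin is the gap between the best and second-best
#' score.
#'
#' @param z Z-score tibble from [zscore()].
#' @param signatures List of [signature_set()] objects (>= 2).
#' @return A `subtype_calls` tibble: `sample_id`, one score column per
#'   subtype, `assigned_subtype`, `margin`, `tie_flag`.
#' @export
assign_subtypes <- function(z, signatures) {
  if (length(signatures) < 2) config_error("need >= 2 signatures to assign subtypes")
  names(signatures) <- purrr::map_chr(signatures, "subtype")
  ord <- order(names(signatures))
  signatures <- signatures[ord]
  scores <- purrr::map(signatures, function(s) signature_score(z, s)$score)
  sm <- do.call(cbind, scores)
  sample_ids <- signature_score(z, signatures[[1]])$sample_id
  best <- apply(sm, 1, which.max)   # first max = lexicographically smallest name
  sorted <- apply(sm, 1, function(r) sort(r, decreasing = TRUE)[1:2])
  margin <- sorted[1, ] - sorted[2, ]
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids),
    tibble::as_tibble(sm),
    tibble::tibble(
      assigned_subtype = names(signatures)[best],
      margin = margin,
      tie_flag = margin == 0
    )
  )
  attr(out, "subtypes") <- names(signatures)
  class(out) <- c("subtype_calls", class(out))
  out
}

#' Cross-tabulate pathological labels against molecular calls
#'
#' Compares an existing (e.g. pathological) labeling with the argmax
#' molecular calls: a contingency table plus a per-sample reassignment list
#' in which low-margin calls are flagged as weak.
#'
#' @param calls A `subtype_calls` tibble from [assign_subtypes()].
#' @param samples Sample metadata tibble covering the same samples; its
#'   `group` column provides the pathological label.
#' @param weak_margin Margin below which a call is flagged weak.
#' @return List of class `reannotation` with `crosstab` (pathology rows x
#'   molecular-call columns) and `reassignments` (per-sample tibble with
#'   `moved` and `weak` flags).
#' @export
reannotate <- function(calls, samples, weak_margin = 0.1) {
  idx <- match(calls$sample_id, samples$sample_id)
  if (anyNA(idx)) {
    config_error(sprintf("calls contain sample(s) absent from the metadata: %s",
                         paste(calls$sample_id[is.na(idx)], collapse = ", ")))
  }
  re <- tibble::tibble(
    sample_id = calls$sample_id,
    pathology = samples$group[idx],
    molecular_call = calls$assigned_subtype,
    margin = calls$margin,
    moved = samples$group[idx] != calls$assigned_subtype,
    weak = calls$margin < weak_margin
  )
  crosstab <- re |>
    dplyr::count(.data$pathology, .data$molecular_call) |>
    tidyr::pivot_wider(names_from = "molecular_call", values_from = "n", values_fill = 0L) |>
    dplyr::arrange(.data$pathology)
  structure(list(crosstab = crosstab, reassignments = re), class = "reannotation")
}

#' @export
print.reannotation <- function(x, ...) {
  cat(sprintf("Reannotation of %d samples (%d moved, %d weak calls)\n",
              nrow(x$reassignments), sum(x$reassignments$moved), sum(x$reassignments$weak)))
  print(x$crosstab)
  invisible(x)
}
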