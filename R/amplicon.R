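#' Genomic neighbors of an anchor gene
#'
#' Returns the genes on the anchor's chromosome whose interval overlaps the
#' half-open window `[anchor_start - window_bp, anchor_end + window_bp)`
#' (0-based half-open coordinates throughout; strand ignored). The anchor is
#' included; results are sorted by start position. With the defaults this
#' reproduces the ERBB2 (HER2) expression-amplicon neighborhood: the anchor
#' plus its neighbors within +/- 51 kb.
#'
#' @param loci Locus tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param anchor_gene Gene id of the anchor.
#' @param window_bp Window size in bp on each side of the anchor interval.
#' @return Character vector of gene ids (anchor included), sorted by start.
#' @export
find_neighbors <- function(loci, anchor_gene, window_bp = 51000) {
  stopifnot(window_bp > 0)
  a <- loci[loci$gene_id == anchor_gene, ]
  if (!nrow(a)) config_error(sprintf("anchor gene '%s' not present in the locus table", anchor_gene))
  w_start <- a$start - window_bp
  w_end <- a$end + window_bp
  hit <- loci$chrom == a$chrom & loci$start < w_end & loci$end > w_start
  nb <- loci[hit, ]
  nb$gene_id[order(nb$start)]
}

#' Call expression amplicons from neighborhood Z-scores
#'
#' A sample is called amplified when the mean z-score over the neighborhood
#' genes strictly exceeds `z_threshold` (default 1.5, the published rule for
#' the HER2 expression amplicon).
#'
#' @param z Z-score tibble from [zscore()] (universe: typically all tumor
#'   samples).
#' @param neighborhood Gene ids of the amplicon neighborhood (e.g. from
#'   [find_neighbors()]).
#' @param z_threshold Strict threshold on the neighborhood mean z.
#' @return An `amplicon_calls` tibble: `sample_id`, `mean_neighborhood_z`,
#'   `amplified`, with the neighborhood in attribute `neighborhood`.
#' @export
call_amplicon <- function(z, neighborhood, z_threshold = 1.5) {
  assert_expr_tbl(z, "z")
  missing <- setdiff(neighborhood, z$gene_id)
  if (length(missing)) {
    config_error(sprintf("neighborhood gene(s) missing from the z-score table: %s",
                         paste(missing, collapse = ", ")))
  }
  m <- tbl_to_matrix(z)
  mz <- colMeans(m[neighborhood, , drop = FALSE])
  out <- tibble::tibble(
    sample_id = colnames(m),
    mean_neighborhood_z = unname(mz),
    amplified = unname(mz > z_threshold)
  )
  attr(out, "neighborhood") <- neighborhood
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("amplicon_calls", class(out))
  out
}
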