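#' Configure a synthetic probe-panel cohort
#'
#' Builds and validates the full parameter set for [generate_cohort()]. The
#' defaults describe a desk-scale cohort with the structure a targeted
#' probe-counting panel produces on a tissue-microarray study: overdispersed
#' counts with sample-to-sample library-size variation, a probe-independent
#' background floor measured by negative-control probes, a block of stably
#' expressed housekeeping genes, universal-RNA (uRNA) control replicates,
#' group-specific marker genes, an 8-gene co-amplified genomic neighborhood,
#' and H-scores coupled to expression (with optional per-group decoupling).
#'
#' @param n_genes Number of gene probes (housekeeping genes are the last
#'   `n_housekeeping` of them).
#' @param n_neg_controls Number of negative-control probes carrying
#'   background-only signal.
#' @param n_housekeeping Number of housekeeping genes (stable, high
#'   expression, no group effects).
#' @param groups Tibble with one row per tumor group: `group` (name),
#'   `n_samples`, `marker_genes` (list-column of gene indices) and
#'   `marker_log2fc` (list-column; scalar or per-marker-gene vector of signed
#'   log2 fold changes relative to the other groups).
#' @param n_normal_samples Number of normal-tissue samples (no marker
#'   effects, group `"normal"`).
#' @param n_urna_controls Number of uRNA control replicates, drawn
#'   independently around the baseline cohort profile.
#' @param library_size_mean,library_size_cv Mean and coefficient of variation
#'   of per-sample sequencing depth, in reads.
#' @param dispersion Negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param background_mean Mean of the Poisson background added to every
#'   probe, in counts.
#' @param amplicon_genes Exactly 8 gene indices forming the co-amplified
#'   neighborhood (anchor first, then its 7 genomic neighbors).
#' @param amplicon_prevalence Probability that a tumor sample carries the
#'   amplicon.
#' @param amplicon_log2fc log2 fold change applied to all 8 amplicon genes in
#'   amplicon-positive samples.
#' @param hscore_genes Gene indices for which per-sample H-scores (0-300) and
#'   IHC categories are emitted.
#' @param hscore_noise_sd Gaussian noise SD added on the H-score scale.
#' @param decoupled_groups Named numeric vector mapping group name to a
#'   protein attenuation factor in `[0, 1]`; latent protein is expression
#'   times this factor (0 = fully decoupled protein, 1 = faithful).
#' @param planted_fail_read_count Sample indices (in generation order) whose
#'   library is downscaled below the sequencing read-count filter.
#' @param planted_fail_low_quality Sample indices whose expression profile is
#'   scrambled and housekeeping signal depressed, so that they fail the
#'   sample-quality filter. Must index tumor or normal samples.
#' @param seed Integer seed; generation is fully reproducible from it.
#'
#' @return A validated `cohort_config` list.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_genes = 500,
                          n_neg_controls = 10,
                          n_housekeeping = 9,
                          groups = default_groups(),
                          n_normal_samples = 10,
                          n_urna_controls = 8,
                          library_size_mean = 3e6,
                          library_size_cv = 0.1,
                          dispersion = 0.1,
                          background_mean = 30,
                          amplicon_genes = 41:48,
                          amplicon_prevalence = 0.1,
                          amplicon_log2fc = 2,
                          hscore_genes = 41L,
                          hscore_noise_sd = 15,
                          decoupled_groups = NULL,
                          planted_fail_read_count = integer(0),
                          planted_fail_low_quality = integer(0),
                          seed = 1L) {
  if (!is.data.frame(groups) && is.list(groups)) {
    # allow the YAML/CLI form: a list of {group, n_samples, marker_genes,
    # marker_log2fc} records
    groups <- dplyr::bind_rows(lapply(groups, function(g) {
      tibble::tibble(
        group = g$group,
        n_samples = as.integer(g$n_samples),
        marker_genes = list(as.integer(unlist(g$marker_genes, use.names = FALSE) %||% integer(0))),
        marker_log2fc = list(as.numeric(unlist(g$marker_log2fc, use.names = FALSE) %||% 0))
      )
    }))
  }
  if (!is.null(decoupled_groups)) decoupled_groups <- unlist(decoupled_groups)
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_neg_controls = as.integer(n_neg_controls),
    n_housekeeping = as.integer(n_housekeeping),
    groups = groups,
    n_normal_samples = as.integer(n_normal_samples),
    n_urna_controls = as.integer(n_urna_controls),
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    dispersion = dispersion,
    background_mean = background_mean,
    amplicon_genes = as.integer(amplicon_genes),
    amplicon_prevalence = amplicon_prevalence,
    amplicon_log2fc = amplicon_log2fc,
    hscore_genes = as.integer(hscore_genes),
    hscore_noise_sd = hscore_noise_sd,
    decoupled_groups = decoupled_groups,
    planted_fail_read_count = as.integer(planted_fail_read_count),
    planted_fail_low_quality = as.integer(planted_fail_low_quality),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_groups <- function() {
  tibble::tibble(
    group = c("A", "B"),
    n_samples = c(30L, 30L),
    marker_genes = list(1:20, 21:40),
    marker_log2fc = list(1.5, 1.5)
  )
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) config_error(sprintf("invalid cohort config field `%s`: %s", field, why))
  }
  chk(cfg$n_genes >= 1, "n_genes", "must be a positive integer")
  chk(cfg$n_neg_controls >= 1, "n_neg_controls", "must be a positive integer")
  chk(cfg$n_housekeeping >= 1 && cfg$n_housekeeping < cfg$n_genes,
      "n_housekeeping", "must be positive and smaller than n_genes")
  g <- cfg$groups
  chk(is.data.frame(g) && nrow(g) >= 1 &&
        all(c("group", "n_samples", "marker_genes", "marker_log2fc") %in% names(g)),
      "groups", "needs columns group, n_samples, marker_genes, marker_log2fc")
  chk(!anyDuplicated(g$group) && all(nzchar(g$group)), "groups", "group names must be unique and non-empty")
  chk(all(g$n_samples >= 1), "groups", "each group needs >=1 sample")
  hk_idx <- housekeeping_indices(cfg)
  for (i in seq_len(nrow(g))) {
    mg <- g$marker_genes[[i]]
    fc <- g$marker_log2fc[[i]]
    chk(all(mg >= 1 & mg <= cfg$n_genes), "groups$marker_genes", "marker index outside gene range")
    chk(!any(mg %in% hk_idx), "groups$marker_genes", "markers may not be housekeeping genes")
    chk(length(fc) == 1L || length(fc) == length(mg),
        "groups$marker_log2fc", "must be scalar or one value per marker gene")
  }
  chk(length(cfg$amplicon_genes) == 8L, "amplicon_genes", "must list exactly 8 genes (anchor + 7 neighbors)")
  chk(all(cfg$amplicon_genes >= 1 & cfg$amplicon_genes <= cfg$n_genes),
      "amplicon_genes", "index outside gene range")
  chk(!any(cfg$amplicon_genes %in% hk_idx), "amplicon_genes", "may not include housekeeping genes")
  chk(!anyDuplicated(cfg$amplicon_genes), "amplicon_genes", "indices must be unique")
  chk(cfg$amplicon_prevalence >= 0 && cfg$amplicon_prevalence <= 1,
      "amplicon_prevalence", "must be a probability in [0, 1]")
  chk(cfg$library_size_mean > 0, "library_size_mean", "must be positive")
  chk(cfg$library_size_cv >= 0, "library_size_cv", "must be non-negative")
  chk(cfg$dispersion > 0, "dispersion", "must be positive")
  chk(cfg$background_mean >= 0, "background_mean", "must be non-negative")
  chk(cfg$hscore_noise_sd >= 0, "hscore_noise_sd", "must be non-negative")
  chk(all(cfg$hscore_genes >= 1 & cfg$hscore_genes <= cfg$n_genes),
      "hscore_genes", "index outside gene range")
  if (!is.null(cfg$decoupled_groups)) {
    chk(!is.null(names(cfg$decoupled_groups)) && all(names(cfg$decoupled_groups) %in% g$group),
        "decoupled_groups", "names must be existing group names")
    chk(all(cfg$decoupled_groups >= 0 & cfg$decoupled_groups <= 1),
        "decoupled_groups", "attenuation factors must lie in [0, 1]")
  }
  n_tissue <- sum(g$n_samples) + cfg$n_normal_samples
  n_total <- n_tissue + cfg$n_urna_controls
  chk(all(cfg$planted_fail_read_count >= 1 & cfg$planted_fail_read_count <= n_total),
      "planted_fail_read_count", "sample index out of range")
  chk(all(cfg$planted_fail_low_quality >= 1 & cfg$planted_fail_low_quality <= n_tissue),
      "planted_fail_low_quality", "must index tumor or normal samples")
  chk(!any(cfg$planted_fail_low_quality %in% cfg$planted_fail_read_count),
      "planted_fail_low_quality", "overlaps planted_fail_read_count")
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed", "must be a single integer")
  structure(cfg, class = "cohort_config")
}

housekeeping_indices <- function(cfg) {
  (cfg$n_genes - cfg$n_housekeeping + 1L):cfg$n_genes
}
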