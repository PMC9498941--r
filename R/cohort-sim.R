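#' Generate a synthetic probe-panel cohort with planted ground truth
#'
#' Draws a full probe-by-sample count matrix plus sample metadata, gene loci
#' and a ground-truth record, according to a [cohort_config()]. Counts follow
#' a gamma-Poisson (negative binomial) model: gene probe counts have mean
#' `library_factor * baseline * 2^(marker + amplicon effects)` with shared
#' dispersion, plus a Poisson background common to every probe; negative
#' control probes carry background only. uRNA control samples are independent
#' draws around the baseline profile. Planted failure samples are downscaled
#' below the sequencing read filter or profile-scrambled (with depressed
#' housekeeping signal) so the two QC filters can be tested against known
#' truth. H-scores for tracked genes follow a saturating monotone map of
#' latent protein (expression times a per-group attenuation factor) with
#' Gaussian noise, clipped to `[0, 300]`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `onco_cohort` with elements
#'   * `counts`: probe count tibble (`probe_id`, `probe_class`,
#'     `housekeeping`, then one integer column per sample);
#'   * `samples`: sample metadata tibble (`sample_id`, `sample_role`,
#'     `group`, plus `hscore_*` / `ihc_*` columns for tracked genes);
#'   * `loci`: gene locus tibble (`gene_id`, `chrom`, `start`, `end`,
#'     `strand`; 0-based half-open);
#'   * `truth`: ground-truth list (`sample_group`, `amplicon_status`,
#'     `qc_should_fail`, `true_marker_sets`, `latent_protein`).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dim(cohort$counts)
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(unclass(config))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  hk_idx <- housekeeping_indices(cfg)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  neg_ids <- sprintf("NEG%02d", seq_len(cfg$n_neg_controls))

  ## --- sample layout: tumor groups, then normals, then uRNA controls
  g <- cfg$groups
  grp_vec <- rep(g$group, g$n_samples)
  role <- c(rep("tumor", length(grp_vec)),
            rep("normal", cfg$n_normal_samples),
            rep("urna_control", cfg$n_urna_controls))
  group <- c(grp_vec,
             rep("normal", cfg$n_normal_samples),
             rep("uRNA", cfg$n_urna_controls))
  n_samples <- length(role)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  is_tissue <- role %in% c("tumor", "normal")

  ## --- baseline expression: lognormal panel, high stable housekeeping block
  mu <- rlnorm(n_genes, meanlog = log(150), sdlog = 1.2)
  mu[hk_idx] <- rlnorm(length(hk_idx), meanlog = log(1500), sdlog = 0.15)

  ## --- per-gene x per-sample log2 effects
  eff <- matrix(0, n_genes, n_samples)
  offset <- 0L
  for (i in seq_len(nrow(g))) {
    cols <- offset + seq_len(g$n_samples[i])
    fc <- g$marker_log2fc[[i]]
    eff[g$marker_genes[[i]], cols] <- eff[g$marker_genes[[i]], cols] + fc
    offset <- offset + g$n_samples[i]
  }
  amp_status <- rep(FALSE, n_samples)
  amp_status[role == "tumor"] <- runif(sum(role == "tumor")) < cfg$amplicon_prevalence
  eff[cfg$amplicon_genes, amp_status] <- eff[cfg$amplicon_genes, amp_status] + cfg$amplicon_log2fc

  ## true per-sample expression; uRNA replicates sit on the baseline profile
  e <- mu * 2^eff
  e[, role == "urna_control"] <- mu

  ## --- library sizes; planted sequencing failures are downscaled
  lib <- rnorm(n_samples, cfg$library_size_mean, cfg$library_size_cv * cfg$library_size_mean)
  lib <- pmax(lib, 0.1 * cfg$library_size_mean)
  lib[cfg$planted_fail_read_count] <- min(0.3 * cfg$library_size_mean, 1e6)
  f <- lib / colSums(e)

  ## --- counts: NB around scaled expression + Poisson background everywhere
  mu_counts <- sweep(e, 2, f, `*`)
  counts <- matrix(
    rnbinom(n_genes * n_samples, mu = as.vector(mu_counts), size = 1 / cfg$dispersion),
    n_genes, n_samples
  )
  if (cfg$background_mean > 0) {
    counts <- counts + matrix(rpois(n_genes * n_samples, cfg$background_mean), n_genes, n_samples)
    neg <- matrix(rpois(cfg$n_neg_controls * n_samples, cfg$background_mean),
                  cfg$n_neg_controls, n_samples)
  } else {
    neg <- matrix(0L, cfg$n_neg_controls, n_samples)
  }

  ## --- low-quality planting: scramble profile, depress housekeeping signal
  for (s in cfg$planted_fail_low_quality) {
    counts[, s] <- counts[sample.int(n_genes), s]
    counts[hk_idx, s] <- round(counts[hk_idx, s] * 0.2)
  }

  ## --- H-scores: saturating map of latent protein, K at the cohort median.
  ## Latent protein tracks the sample's realized depth-normalized transcript
  ## level (not the group mean), so within-group mRNA-protein correlation is
  ## positive under attenuation 1 and vanishes under attenuation 0.
  atten <- setNames(rep(1, nrow(g)), g$group)
  if (!is.null(cfg$decoupled_groups)) {
    atten[names(cfg$decoupled_groups)] <- cfg$decoupled_groups
  }
  atten <- c(atten, normal = 1)
  samples_tbl <- tibble::tibble(sample_id = sample_ids, sample_role = role, group = group)
  latent_protein <- list()
  for (gi in cfg$hscore_genes) {
    gid <- gene_ids[gi]
    latent <- rep(NA_real_, n_samples)
    latent[is_tissue] <- counts[gi, is_tissue] / f[is_tissue] * unname(atten[group[is_tissue]])
    k <- median(latent[is_tissue])
    if (!is.finite(k) || k <= 0) k <- 1
    # H-scores are reported at one-decimal precision, as pathologists do
    h <- round(hscore_map(latent, k, noise_sd = cfg$hscore_noise_sd), 1)
    samples_tbl[[paste0("hscore_", gid)]] <- h
    samples_tbl[[paste0("ihc_", gid)]] <- hscore_to_ihc(h)
    latent_protein[[gid]] <- setNames(latent[is_tissue], sample_ids[is_tissue])
  }

  ## --- assemble tables
  full <- rbind(counts, neg)
  storage.mode(full) <- "integer"
  colnames(full) <- sample_ids
  counts_tbl <- dplyr::bind_cols(
    tibble::tibble(
      probe_id = c(gene_ids, neg_ids),
      probe_class = c(rep("gene", n_genes), rep("neg_ctrl", cfg$n_neg_controls)),
      housekeeping = c(seq_len(n_genes) %in% hk_idx, rep(FALSE, cfg$n_neg_controls))
    ),
    tibble::as_tibble(full)
  )

  truth <- list(
    sample_group = setNames(group, sample_ids),
    amplicon_status = setNames(amp_status, sample_ids),
    qc_should_fail = setNames(ifelse(
      seq_len(n_samples) %in% cfg$planted_fail_read_count, "seq_fail",
      ifelse(seq_len(n_samples) %in% cfg$planted_fail_low_quality, "quality_fail", "pass")
    ), sample_ids),
    true_marker_sets = marker_sets_from_config(cfg, gene_ids),
    latent_protein = latent_protein
  )

  structure(
    list(
      counts = counts_tbl,
      samples = samples_tbl,
      loci = make_loci(cfg, gene_ids),
      truth = truth
    ),
    class = "onco_cohort"
  )
}

marker_sets_from_config <- function(cfg, gene_ids) {
  g <- cfg$groups
  sets <- purrr::map(seq_len(nrow(g)), function(i) {
    mg <- g$marker_genes[[i]]
    fc <- rep_len(g$marker_log2fc[[i]], length(mg))
    list(high = gene_ids[mg[fc > 0]], low = gene_ids[mg[fc < 0]])
  })
  setNames(sets, g$group)
}

# Gene loci: the 8 amplicon genes sit on chr17 inside a +/- 51 kb window of
# the anchor (ERBB2-like coordinates); all other genes are spread over other
# chromosomes, far from one another.
make_loci <- function(cfg, gene_ids) {
  n_genes <- cfg$n_genes
  chrom <- paste0("chr", 1 + (seq_len(n_genes) %% 16))
  chrom[chrom == "chr17"] <- "chr18"
  start <- 1e6 + 2e6 * seq_len(n_genes)
  end <- start + 20000
  amp <- cfg$amplicon_genes
  anchor_start <- 39687914; anchor_end <- 39728658
  chrom[amp] <- "chr17"
  start[amp[1]] <- anchor_start; end[amp[1]] <- anchor_end
  up <- amp[2:4]; down <- amp[5:8]
  start[up] <- anchor_start - 12000 * seq_along(up) - 5000
  end[up] <- start[up] + 5000
  start[down] <- anchor_end + 12000 * (seq_along(down) - 1) + 1000
  end[down] <- start[down] + 5000
  tibble::tibble(
    gene_id = gene_ids, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = "+"
  )
}

#' Saturating H-score link
#'
#' `H = 300 * latent / (latent + k)` plus optional Gaussian noise, clipped to
#' `[0, 300]`. With `k` at the cohort-median latent protein level the median
#' sample scores about 150. Monotone non-decreasing in `latent` at
#' `noise_sd = 0`.
#'
#' @param latent Non-negative latent protein levels.
#' @param k Half-saturation constant (positive).
#' @param noise_sd Gaussian noise SD on the H-score scale.
#' @return H-scores in `[0, 300]` (NA preserved).
#' @export
hscore_map <- function(latent, k, noise_sd = 0) {
  h <- 300 * latent / (latent + k)
  if (noise_sd > 0) h <- h + rnorm(length(h), 0, noise_sd)
  pmin(300, pmax(0, h))
}

#' Map an H-score to an IHC intensity category
#'
#' Default bins: 0 for H < 1, 1+ for 1-100, 2+ for (100, 200], 3+ for > 200.
#' Used by the cohort generator and as a fallback when a metadata table
#' carries H-scores but no pathologist IHC grades.
#'
#' @param h H-scores in `[0, 300]`.
#' @param breaks Increasing cut points (defaults `c(1, 100, 200)`).
#' @return Integer categories in `{0, 1, 2, 3}` (NA preserved).
#' @export
hscore_to_ihc <- function(h, breaks = c(1, 100, 200)) {
  stopifnot(length(breaks) == 3, !is.unsorted(breaks))
  out <- ifelse(h < breaks[1], 0L, ifelse(h <= breaks[2], 1L, ifelse(h <= breaks[3], 2L, 3L)))
  as.integer(out)
}

#' Write a synthetic cohort to disk
#'
#' Writes `counts.tsv`, `samples.tsv`, `loci.bed` (BED6, 0-based half-open),
#' and `truth.json` under `out_dir`, plus a `manifest.json` listing each file
#' with its MD5 checksum. The manifest carries no timestamps, so identical
#' cohorts produce byte-identical manifests.
#'
#' @param cohort An `onco_cohort` from [generate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!inherits(cohort, "onco_cohort")) config_error("`cohort` must come from generate_cohort()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) io_error(sprintf("cannot create output directory '%s'", out_dir))
  paths <- c(
    counts = file.path(out_dir, "counts.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    loci = file.path(out_dir, "loci.bed"),
    truth = file.path(out_dir, "truth.json")
  )
  write_counts(cohort$counts, paths["counts"])
  write_metadata(cohort$samples, paths["samples"])
  write_bed(cohort$loci, paths["loci"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    files = purrr::map2(names(paths), unname(paths), function(nm, p) {
      list(name = basename(p), role = nm, md5 = unname(tools::md5sum(p)))
    }),
    n_probes = nrow(cohort$counts),
    n_samples = nrow(cohort$samples)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
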