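#' Assemble a pipeline run configuration
#'
#' Collects input paths, stage parameters and the seed into a single
#' validated list. Every stage of [run_pipeline()] reads its inputs from
#' disk and writes its outputs under `output_dir`, so stagewise and
#' monolithic runs produce byte-identical files.
#'
#' @param counts,metadata,loci,signatures,blacklist Input file paths
#'   (`loci`, `signatures`, `blacklist` optional; `counts`/`metadata` may be
#'   omitted when `simulate` is given).
#' @param output_dir Output directory.
#' @param seed Integer seed (used by the simulate stage).
#' @param qc Named list of [qc_config()] overrides.
#' @param marker Named list of [select_markers()] settings (kept in the
#'   manifest for provenance).
#' @param amplicon Named list: `anchor`, `window_bp`, `z_threshold`,
#'   `include_anchor`.
#' @param concordance Named list: `gene` (H-score-tracked gene; autodetected
#'   from `hscore_*` metadata columns when NULL), `rank_gap`, `method`.
#' @param simulate Optional named list of [cohort_config()] arguments; when
#'   present the pipeline generates and writes a synthetic cohort first and
#'   analyses it.
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, metadata = NULL, loci = NULL,
                       signatures = NULL, blacklist = NULL,
                       output_dir = "oncopanel_out", seed = 1L,
                       qc = list(), marker = list(),
                       amplicon = list(anchor = NULL, window_bp = 51000,
                                       z_threshold = 1.5, include_anchor = TRUE),
                       concordance = list(gene = NULL, rank_gap = 0.3, method = "pearson"),
                       simulate = NULL) {
  cfg <- list(
    counts = counts, metadata = metadata, loci = loci,
    signatures = signatures, blacklist = blacklist,
    output_dir = output_dir, seed = as.integer(seed),
    qc = qc, marker = marker,
    amplicon = modifyList(list(anchor = NULL, window_bp = 51000,
                               z_threshold = 1.5, include_anchor = TRUE), amplicon),
    concordance = modifyList(list(gene = NULL, rank_gap = 0.3, method = "pearson"), concordance),
    simulate = simulate
  )
  if (is.null(cfg$simulate)) {
    for (f in c("counts", "metadata")) {
      if (is.null(cfg[[f]])) config_error(sprintf("run_config: `%s` path is required (or supply `simulate`)", f))
      if (!file.exists(cfg[[f]])) io_error(sprintf("run_config: %s file '%s' does not exist", f, cfg[[f]]))
    }
  } else {
    # simulated inputs land in <output_dir>/sim; point unset paths there so
    # stagewise invocations resolve the same files as a monolithic run
    sim_dir <- file.path(cfg$output_dir, "sim")
    cfg$counts <- cfg$counts %||% file.path(sim_dir, "counts.tsv")
    cfg$metadata <- cfg$metadata %||% file.path(sim_dir, "samples.tsv")
    cfg$loci <- cfg$loci %||% file.path(sim_dir, "loci.bed")
    if (is.null(cfg$signatures)) {
      cfg$signatures <- file.path(sim_dir, "signatures.tsv")
      cfg$signatures_auto <- TRUE
    }
    if (is.null(cfg$amplicon$anchor)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      gi <- do.call(cohort_config, sim_args)$amplicon_genes[1]
      cfg$amplicon$anchor <- sprintf("G%04d", gi)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]. `overrides` (typically
#' command-line flags) take precedence over file values; each override is
#' logged.
#'
#' @param path YAML file.
#' @param overrides Named list of scalar overrides using dotted paths for
#'   nested keys (e.g. `qc.min_total_reads`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) io_error(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    inform(sprintf("flag overrides config: %s = %s", key, format(overrides[[key]])))
    if (length(parts) == 1) {
      raw[[parts]] <- overrides[[key]]
    } else {
      raw[[parts[1]]][[parts[2]]] <- overrides[[key]]
    }
  }
  do.call(run_config, raw)
}

PIPELINE_STAGES <- c("simulate", "qc", "normalize", "score", "classify", "amplicon", "concord")

#' Run the analysis pipeline
#'
#' Executes the requested stages in the fixed order simulate (optional) ->
#' qc -> normalize -> score -> classify -> amplicon -> concord. Each stage
#' reads its inputs from disk and writes TSV outputs under
#' `cfg$output_dir`; a `manifest.json` listing every output with its MD5
#' checksum, the parameters, and the seed is written at the end. Identical
#' config + seed yields a byte-identical manifest. A stage failure aborts
#' with the stage name after writing a partial manifest.
#'
#' @param cfg A [run_config()].
#' @param stages `"all"` or a subset of
#'   `c("simulate", "qc", "normalize", "score", "classify", "amplicon",
#'   "concord")`.
#' @return Path to the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, stages = "all") {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  if (identical(stages, "all")) {
    stages <- PIPELINE_STAGES
    if (is.null(cfg$simulate)) stages <- setdiff(stages, "simulate")
  }
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) config_error(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  done <- character(0)
  for (stage in stages) {
    fn <- switch(stage,
      simulate = stage_simulate, qc = stage_qc, normalize = stage_normalize,
      score = stage_score, classify = stage_classify,
      amplicon = stage_amplicon, concord = stage_concord
    )
    res <- tryCatch(fn(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      write_manifest(cfg, done, error = list(stage = stage, message = conditionMessage(res)))
      onco_abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(res)),
                 "oncopanel_stage_error")
    }
    if (!is.null(res$skipped)) {
      inform(sprintf("stage '%s' skipped: %s", stage, res$skipped))
    } else {
      cfg <- res$cfg %||% cfg
      done <- c(done, res$files)
      inform(sprintf("stage '%s' wrote: %s", stage, paste(basename(res$files), collapse = ", ")))
    }
  }
  invisible(write_manifest(cfg, done))
}

out_path <- function(cfg, name) file.path(cfg$output_dir, name)

stage_simulate <- function(cfg) {
  sim_args <- cfg$simulate
  if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
  cohort <- generate_cohort(do.call(cohort_config, sim_args))
  sim_dir <- out_path(cfg, "sim")
  write_cohort(cohort, sim_dir)
  sig_path <- file.path(sim_dir, "signatures.tsv")
  sets <- purrr::keep(cohort$truth$true_marker_sets,
                      function(s) length(s$high) + length(s$low) > 0)
  if (length(sets) >= 2) {
    sigs <- purrr::imap(sets, function(s, nm) signature_set(nm, high = s$high, low = s$low))
    write_signatures(sigs, sig_path)
  }
  list(files = c(file.path(sim_dir, c("counts.tsv", "samples.tsv", "loci.bed",
                                      "truth.json", "manifest.json")),
                 if (file.exists(sig_path)) sig_path))
}

pipeline_qc <- function(cfg) {
  counts <- suppressMessages(read_counts(cfg$counts))
  samples <- suppressMessages(read_metadata(cfg$metadata))
  res <- run_qc(counts, samples, do.call(qc_config, cfg$qc))
  list(counts = counts, samples = samples, qc = res)
}

stage_qc <- function(cfg) {
  res <- pipeline_qc(cfg)$qc
  report <- res$report
  report$housekeeping_threshold <- res$housekeeping_threshold
  p <- out_path(cfg, "qc_report.tsv")
  write_table(report, p)
  list(files = p)
}

stage_normalize <- function(cfg) {
  res <- pipeline_qc(cfg)$qc
  p <- out_path(cfg, "expression.tsv")
  write_table(res$expr_pass, p)
  list(files = p)
}

read_stage_expr <- function(cfg) {
  p <- out_path(cfg, "expression.tsv")
  if (!file.exists(p)) io_error("expression.tsv not found; run the 'normalize' stage first")
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
}

stage_score <- function(cfg) {
  expr <- read_stage_expr(cfg)
  samples <- suppressMessages(read_metadata(cfg$metadata))
  universe <- intersect(
    samples$sample_id[samples$sample_role %in% c("tumor", "normal")],
    sample_cols(expr, "gene_id")
  )
  z <- zscore(expr, universe)
  p <- out_path(cfg, "zscores.tsv")
  write_table(z, p)
  list(files = p)
}

stage_classify <- function(cfg) {
  if (is.null(cfg$signatures)) return(list(skipped = "no signature file configured"))
  if (!file.exists(cfg$signatures)) {
    if (isTRUE(cfg$signatures_auto)) {
      return(list(skipped = "simulated cohort emitted no marker signatures"))
    }
    io_error(sprintf("signature file '%s' does not exist", cfg$signatures))
  }
  zp <- out_path(cfg, "zscores.tsv")
  if (!file.exists(zp)) io_error("zscores.tsv not found; run the 'score' stage first")
  z <- readr::read_tsv(zp, show_col_types = FALSE, progress = FALSE)
  sigs <- suppressMessages(read_signatures(cfg$signatures))
  samples <- suppressMessages(read_metadata(cfg$metadata))
  calls <- suppressMessages(assign_subtypes(z, sigs))
  p_calls <- out_path(cfg, "subtype_calls.tsv")
  write_table(calls, p_calls)
  tumor <- samples$sample_id[samples$sample_role == "tumor"]
  re <- reannotate(calls[calls$sample_id %in% tumor, ], samples)
  p_cross <- out_path(cfg, "crosstab.tsv")
  write_table(re$crosstab, p_cross)
  list(files = c(p_calls, p_cross))
}

stage_amplicon <- function(cfg) {
  if (is.null(cfg$loci) || is.null(cfg$amplicon$anchor)) {
    return(list(skipped = "no locus file / anchor gene configured"))
  }
  expr <- read_stage_expr(cfg)
  samples <- suppressMessages(read_metadata(cfg$metadata))
  loci <- suppressMessages(read_bed(cfg$loci))
  tumor <- intersect(samples$sample_id[samples$sample_role == "tumor"],
                     sample_cols(expr, "gene_id"))
  z <- zscore(expr[, c("gene_id", tumor)], tumor)
  nb <- find_neighbors(loci, cfg$amplicon$anchor, cfg$amplicon$window_bp)
  if (!isTRUE(cfg$amplicon$include_anchor)) nb <- setdiff(nb, cfg$amplicon$anchor)
  nb <- intersect(nb, z$gene_id)
  calls <- call_amplicon(z, nb, cfg$amplicon$z_threshold)
  p <- out_path(cfg, "amplicon_calls.tsv")
  write_table(calls, p)
  list(files = p)
}

stage_concord <- function(cfg) {
  expr <- read_stage_expr(cfg)
  samples <- suppressMessages(read_metadata(cfg$metadata))
  gene <- cfg$concordance$gene
  if (is.null(gene)) {
    hcols <- grep("^hscore_", names(samples), value = TRUE)
    if (!length(hcols)) return(list(skipped = "no H-score columns in the metadata"))
    gene <- sub("^hscore_", "", hcols[1])
  }
  rows <- suppressMessages(
    mrna_protein_by_group(expr, samples, gene, method = cfg$concordance$method)
  )
  if (nrow(rows) >= 3) rows <- discordance_flags(rows, cfg$concordance$rank_gap)
  rows$pooled_r <- attr(rows, "pooled_r")
  icol <- paste0("ihc_", gene)
  if (icol %in% names(samples)) {
    pos <- ihc_positivity(samples, gene)
    rows <- dplyr::left_join(rows, pos[, c("group", "pct_ihc_positive")], by = "group")
  }
  p <- out_path(cfg, "group_protein.tsv")
  write_table(rows, p)
  list(files = p)
}

write_manifest <- function(cfg, files, error = NULL) {
  files <- unique(files[file.exists(files)])
  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[c("qc", "marker", "amplicon", "concordance", "simulate")],
    inputs = cfg[c("counts", "metadata", "loci", "signatures", "blacklist")],
    outputs = purrr::map(files, function(p) {
      nm <- if (startsWith(p, paste0(cfg$output_dir, "/"))) {
        substring(p, nchar(cfg$output_dir) + 2L)
      } else basename(p)
      list(name = nm, md5 = unname(tools::md5sum(p)))
    })
  )
  if (!is.null(error)) manifest$error <- error
  path <- out_path(cfg, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  path
}
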