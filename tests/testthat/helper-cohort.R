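# Small cohort configurations used across test files. Kept deliberately tiny
# so the full suite stays fast; test-acceptance.R uses the study-scale cohorts.

small_groups <- function(n_per_group = 20, k = 2, markers_per_group = 5, log2fc = 1.5) {
  tibble::tibble(
    group = LETTERS[seq_len(k)],
    n_samples = rep(as.integer(n_per_group), k),
    marker_genes = lapply(seq_len(k), function(i) ((i - 1) * markers_per_group + 1):(i * markers_per_group)),
    marker_log2fc = rep(list(log2fc), k)
  )
}

small_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 60,
    groups = small_groups(),
    n_normal_samples = 4,
    n_urna_controls = 4,
    amplicon_genes = 31:38,
    hscore_genes = 31L,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

`%||%` <- rlang::`%||%`

# expression-style tibble from a named matrix
expr_tbl <- function(m, id = "gene_id") {
  dplyr::bind_cols(tibble::tibble(!!id := rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

random_expr <- function(n_genes, n_samples, seed = 1, prefix = "g") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 8, 2), n_genes, n_samples,
                dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    expr_tbl(abs(m))
  })
}
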