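# Internal helpers shared across modules. All heavy numerics run on plain
# matrices; tibbles live at the interface only.

onco_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "oncopanel_error"), ...)
}

config_error <- function(msg, ...) onco_abort(msg, "oncopanel_config_error", ...)
parse_error  <- function(msg, ...) onco_abort(msg, "oncopanel_parse_error", ...)
io_error     <- function(msg, ...) onco_abort(msg, "oncopanel_io_error", ...)

# value table (id column + one numeric column per sample) -> numeric matrix
tbl_to_matrix <- function(tbl, id_col = 1L) {
  m <- as.matrix(tbl[, setdiff(seq_along(tbl), id_col), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tbl[[id_col]])
  m
}

matrix_to_tbl <- function(m, id_name = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), out)
}

# columns of an expression/count table that hold per-sample values
sample_cols <- function(tbl, id_cols) setdiff(names(tbl), id_cols)

assert_expr_tbl <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || ncol(expr) < 2L) {
    config_error(sprintf("`%s` must be a table with an id column plus >=1 sample column", arg))
  }
  invisible(expr)
}

# sample standard deviation (n-1), NA-safe for length-1 input
sample_sd <- function(x) stats::sd(x)

# percentile ranks in [0, 1], average ties
pct_rank <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

`%||%` <- rlang::`%||%`
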