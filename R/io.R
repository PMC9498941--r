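#' Read a probe-by-sample count table
#'
#' Expects a tab-delimited file with columns `probe_id`, `probe_class`
#' (`gene` or `neg_ctrl`), `housekeeping` (0/1, gene probes only), then one
#' integer column per sample. Lines starting with `#` are comments.
#' Duplicate probe or sample identifiers, negative or non-integer counts,
#' and housekeeping flags on control probes are rejected with the offending
#' row/column named.
#'
#' @param path Path to the counts TSV.
#' @return A validated tibble (`probe_id`, `probe_class`, `housekeeping`
#'   logical, then integer sample columns).
#' @export
read_counts <- function(path) {
  hdr <- tsv_header(path)
  dup <- hdr[duplicated(hdr)]
  if (length(dup)) {
    parse_error(sprintf("duplicated column name(s) in '%s': %s",
                        path, paste(unique(dup), collapse = ", ")))
  }
  need <- c("probe_id", "probe_class", "housekeeping")
  if (!identical(hdr[1:3], need)) {
    parse_error(sprintf("malformed counts header in '%s': first columns must be %s",
                        path, paste(need, collapse = ", ")))
  }
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(tbl$probe_id)) {
    parse_error(sprintf("duplicated probe_id in '%s': %s", path,
                        tbl$probe_id[duplicated(tbl$probe_id)][1]))
  }
  if (!all(tbl$probe_class %in% c("gene", "neg_ctrl"))) {
    bad <- which(!tbl$probe_class %in% c("gene", "neg_ctrl"))[1]
    parse_error(sprintf("unknown probe_class '%s' at row %d of '%s'",
                        tbl$probe_class[bad], bad, path))
  }
  smp <- sample_cols(tbl, need)
  if (!length(smp)) parse_error(sprintf("no sample columns in '%s'", path))
  for (cn in smp) {
    v <- tbl[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      parse_error(sprintf("non-numeric or missing count in column '%s' of '%s'", cn, path))
    }
    bad <- which(v < 0 | v != floor(v))[1]
    if (!is.na(bad)) {
      parse_error(sprintf("negative or non-integer count %s at row %d, column '%s' of '%s'",
                          format(v[bad]), bad, cn, path))
    }
    tbl[[cn]] <- as.integer(v)
  }
  tbl$housekeeping <- as.logical(tbl$housekeeping)
  validate_counts(tbl)
  inform(sprintf("read %d probes x %d samples from '%s'", nrow(tbl), length(smp), path))
  tbl
}

validate_counts <- function(tbl) {
  if (!any(tbl$probe_class == "gene") || !any(tbl$probe_class == "neg_ctrl")) {
    parse_error("count table needs at least one gene probe and one neg_ctrl probe")
  }
  if (any(tbl$housekeeping & tbl$probe_class != "gene")) {
    parse_error("housekeeping flag set on a non-gene probe")
  }
  invisible(tbl)
}

#' Write a probe count table
#'
#' Inverse of [read_counts()]; the housekeeping flag is written as 0/1.
#'
#' @param counts Count tibble as returned by [read_counts()] /
#'   [generate_cohort()].
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  out <- counts
  out$housekeeping <- as.integer(out$housekeeping)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `sample_role` (one of `tumor`,
#' `normal`, `urna_control`, `multitissue_control`), `group`, and optional
#' `hscore_<gene>` (reals in `[0, 300]`) and `ihc_<gene>` (integers 0-3)
#' columns.
#'
#' @param path Path to the metadata TSV.
#' @return A validated tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "sample_role", "group")
  if (!all(need %in% names(tbl))) {
    parse_error(sprintf("metadata '%s' must have columns %s", path, paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tbl$sample_id)) {
    parse_error(sprintf("duplicated sample_id in '%s': %s", path,
                        tbl$sample_id[duplicated(tbl$sample_id)][1]))
  }
  roles <- c("tumor", "normal", "urna_control", "multitissue_control")
  if (!all(tbl$sample_role %in% roles)) {
    bad <- setdiff(unique(tbl$sample_role), roles)[1]
    parse_error(sprintf("unknown sample_role '%s' in '%s'", bad, path))
  }
  tissue <- tbl$sample_role %in% c("tumor", "normal")
  if (any(tissue & (is.na(tbl$group) | !nzchar(tbl$group)))) {
    parse_error(sprintf("empty group for a tumor/normal sample in '%s'", path))
  }
  for (cn in grep("^hscore_", names(tbl), value = TRUE)) {
    v <- tbl[[cn]]
    if (any(v < 0 | v > 300, na.rm = TRUE)) {
      parse_error(sprintf("H-score outside [0, 300] in column '%s' of '%s'", cn, path))
    }
  }
  for (cn in grep("^ihc_", names(tbl), value = TRUE)) {
    v <- tbl[[cn]]
    if (any(!v %in% c(0:3, NA))) {
      parse_error(sprintf("IHC category outside {0,1,2,3} in column '%s' of '%s'", cn, path))
    }
    tbl[[cn]] <- as.integer(v)
  }
  inform(sprintf("read %d samples from '%s'", nrow(tbl), path))
  tbl
}

#' @rdname read_metadata
#' @param samples Metadata tibble.
#' @export
write_metadata <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read gene loci from a BED file
#'
#' BED6, 0-based half-open. Parsed through rtracklayer and converted back to
#' 0-based coordinates in the returned tibble. Strand `*` is reported as
#' `"."`.
#'
#' @param path Path to a BED file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) parse_error(sprintf("cannot parse BED '%s': %s", path, conditionMessage(e)))
  )
  tbl <- tibble::tibble(
    gene_id = if (!is.null(gr$name)) gr$name else as.character(seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr)))
  )
  if (any(tbl$start >= tbl$end)) {
    bad <- which(tbl$start >= tbl$end)[1]
    parse_error(sprintf("interval with start >= end at record %d of '%s'", bad, path))
  }
  if (anyDuplicated(tbl$gene_id)) {
    parse_error(sprintf("duplicated gene_id in '%s'", path))
  }
  inform(sprintf("read %d loci from '%s'", nrow(tbl), path))
  tbl
}

#' @rdname read_bed
#' @param loci Locus tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
write_bed <- function(loci, path) {
  if (any(loci$start >= loci$end)) io_error("locus with start >= end cannot be written")
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = sub("^\\.$", "*", loci$strand),
    name = loci$gene_id,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Signed gene signatures
#'
#' A signature set names a subtype plus its `high` markers (expected up in
#' the subtype) and `low` markers (expected down); scoring averages `+z` over
#' high genes and `-z` over low genes.
#'
#' @param subtype Subtype name.
#' @param high,low Character vectors of gene ids; disjoint, union non-empty.
#' @return A `signature_set` object.
#' @export
signature_set <- function(subtype, high = character(0), low = character(0)) {
  if (!nzchar(subtype)) config_error("signature subtype name must be non-empty")
  if (length(intersect(high, low))) {
    config_error(sprintf("signature '%s': genes in both high and low: %s",
                         subtype, paste(intersect(high, low), collapse = ", ")))
  }
  if (!length(high) && !length(low)) {
    config_error(sprintf("signature '%s' has no genes", subtype))
  }
  structure(list(subtype = subtype, high = unique(high), low = unique(low)),
            class = "signature_set")
}

#' Read signed signatures from a TSV
#'
#' Three columns: `subtype`, `gene`, `direction` (`high` or `low`).
#'
#' @param path Path to the signature TSV.
#' @return Named list of [signature_set()] objects.
#' @export
read_signatures <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  need <- c("subtype", "gene", "direction")
  if (!all(need %in% names(tbl))) {
    parse_error(sprintf("signature file '%s' must have columns %s", path,
                        paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$direction), c("high", "low"))
  if (length(bad)) {
    parse_error(sprintf("unknown direction token '%s' in '%s' (expected high/low)", bad[1], path))
  }
  sets <- tbl |>
    dplyr::group_by(.data$subtype) |>
    dplyr::group_map(function(d, key) {
      signature_set(key$subtype,
                    high = d$gene[d$direction == "high"],
                    low = d$gene[d$direction == "low"])
    })
  names(sets) <- sort(unique(tbl$subtype))
  inform(sprintf("read %d signatures (%d gene rows) from '%s'", length(sets), nrow(tbl), path))
  sets
}

#' @rdname read_signatures
#' @param signatures Named list of [signature_set()] objects.
#' @export
write_signatures <- function(signatures, path) {
  tbl <- purrr::map_dfr(signatures, function(s) {
    tibble::tibble(
      subtype = s$subtype,
      gene = c(s$high, s$low),
      direction = c(rep("high", length(s$high)), rep("low", length(s$low)))
    )
  })
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write any report table as TSV
#'
#' Deterministic column order (as given) and UNIX line endings.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}

# first non-comment line of a TSV, split into fields
tsv_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) parse_error(sprintf("'%s' has no header line", path))
    if (!startsWith(line, "#")) return(strsplit(line, "\t", fixed = TRUE)[[1]])
  }
}
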