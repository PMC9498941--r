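# helper: counts tibble from a gene matrix and a negative-control matrix
counts_from <- function(genes, negs, hk = rep(FALSE, nrow(genes))) {
  stopifnot(ncol(genes) == ncol(negs))
  ids <- c(sprintf("G%02d", seq_len(nrow(genes))), sprintf("N%02d", seq_len(nrow(negs))))
  m <- rbind(genes, negs)
  colnames(m) <- colnames(genes) %||% sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(probe_id = ids,
                   probe_class = rep(c("gene", "neg_ctrl"), c(nrow(genes), nrow(negs))),
                   housekeeping = c(hk, rep(FALSE, nrow(negs)))),
    tibble::as_tibble(m)
  )
}
`%||%` <- rlang::`%||%`

test_that("the sequencing filter applies strict read-count and relative-SD bounds", {
  # sample a: 1.4e6 reads -> fail; b: exactly 1.5e6 -> pass; c: zero variance -> fail
  genes <- cbind(a = c(1e6, 4e5 - 20), b = c(1e6, 5e5 - 20), c = c(1000, 1000))
  negs <- matrix(10, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- sequencing_quality_filter(counts_from(genes, negs))
  expect_equal(res$report$total_reads, c(1.4e6, 1.5e6, 2020))
  expect_equal(res$report$seq_pass, c(FALSE, TRUE, FALSE))
  expect_equal(colnames(res$counts)[-(1:3)], "b")

  # zero-total sample: rel_sd undefined, excluded
  z <- counts_from(cbind(d = c(0, 0)), matrix(0, 1, 1, dimnames = list(NULL, "d")))
  rz <- sequencing_quality_filter(z)
  expect_true(is.na(rz$report$rel_sd))
  expect_false(rz$report$seq_pass)

  # planted failures in a synthetic cohort are exactly the removed samples
  co <- generate_cohort(small_config(seed = 81, planted_fail_read_count = c(3L, 17L)))
  r <- sequencing_quality_filter(co$counts)
  m <- as.matrix(co$counts[, -(1:3)])
  expect_equal(r$report$total_reads, unname(colSums(m)))
  expect_equal(r$report$rel_sd, unname(apply(m, 2, function(x) sd(x) / mean(x))))
  expect_setequal(r$report$sample_id[!r$report$seq_pass], c("S0003", "S0017"))
})

test_that("background subtraction matches the mean-of-negative-controls rule", {
  genes <- cbind(s1 = c(100, 10))
  negs <- cbind(s1 = c(20, 40))
  adj <- subtract_background(counts_from(genes, negs))
  expect_equal(adj$s1, c(70, 0))   # 100 - 30; clamp at zero

  withr::with_seed(5, {
    g <- matrix(rpois(50 * 10, 200), 50, 10)
    n <- matrix(rpois(5 * 10, 30), 5, 10)
  })
  colnames(g) <- colnames(n) <- sprintf("s%02d", 1:10)
  got <- as.matrix(subtract_background(counts_from(g, n))[, -1])
  # independently coded loop oracle
  want <- matrix(0, 50, 10)
  for (j in 1:10) {
    b <- mean(n[, j])
    for (i in 1:50) want[i, j] <- max(g[i, j] - b, 0)
  }
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("adjCPM scales every sample to one million and is scale invariant", {
  one <- expr_tbl(matrix(5, 1, 1, dimnames = list("g1", "s1")))
  expect_equal(adjcpm(one)$s1, 1e6)

  x <- random_expr(40, 6, seed = 6)
  y <- x; y[[3]] <- y[[3]] * 2
  expect_equal(adjcpm(x)[[3]], adjcpm(y)[[3]])
  sums <- colSums(as.matrix(adjcpm(x)[, -1]))
  expect_equal(unname(sums), rep(1e6, 6), tolerance = 1e-6)

  bad <- expr_tbl(matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "s1")))
  expect_error(adjcpm(bad), "zero post-subtraction total")
  expect_error(adjcpm(bad), "s1")
})

test_that("upper-quartile normalization equalizes the positive 75th percentile", {
  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  two <- cbind(m, s2 = 2 * m[, 1])
  colnames(two) <- c("s1", "s2")
  out <- uq_normalize(expr_tbl(two))
  expect_equal(out$s1, out$s2)

  same <- expr_tbl(cbind(s1 = m[, 1], s2 = m[, 1]) |> `rownames<-`(paste0("g", 1:4)))
  expect_equal(uq_normalize(same), same)

  x <- random_expr(80, 7, seed = 7)
  x[2, 3] <- 0   # zeros are excluded from the quantile
  out <- uq_normalize(x)
  mo <- as.matrix(out[, -1])
  # brute-force oracle: each sample's positive 75th percentile hits the
  # median of the input per-sample quantiles
  mi <- as.matrix(x[, -1])
  uqs <- apply(mi, 2, function(v) quantile(v[v > 0], 0.75, type = 7))
  target <- median(uqs)
  got <- apply(mo, 2, function(v) quantile(v[v > 0], 0.75, type = 7))
  expect_equal(unname(got), rep(target, 7), tolerance = 1e-9)
})

test_that("log transform is log2(x + 1) and rejects negatives", {
  x <- expr_tbl(matrix(c(0, 1, 1023), 3, 1, dimnames = list(paste0("g", 1:3), "s1")))
  expect_equal(log_transform(x)$s1, c(0, 1, 10))
  neg <- expr_tbl(matrix(-1, 1, 1, dimnames = list("g1", "s1")))
  expect_error(log_transform(neg), class = "oncopanel_invariant_error")
})

test_that("the uRNA reference is the mean profile and concentrates like 1/sqrt(n)", {
  samples <- tibble::tibble(sample_id = c("u1", "u2", "t1"),
                            sample_role = c("urna_control", "urna_control", "tumor"),
                            group = c("uRNA", "uRNA", "A"))
  m <- cbind(u1 = c(2, 4), u2 = c(4, 8), t1 = c(9, 9))
  rownames(m) <- c("g1", "g2")
  ref <- urna_reference(expr_tbl(m), samples)
  expect_equal(ref$reference, c(3, 6))
  expect_error(urna_reference(expr_tbl(m[, 1, drop = FALSE]), samples), ">=2 uRNA")

  withr::with_seed(8, {
    true <- rnorm(100, 8, 2)
    n <- 12; sigma <- 0.5
    um <- sapply(seq_len(n), function(i) true + rnorm(100, 0, sigma))
  })
  colnames(um) <- sprintf("u%02d", seq_len(n))
  rownames(um) <- sprintf("g%03d", seq_len(100))
  st <- tibble::tibble(sample_id = colnames(um), sample_role = "urna_control", group = "uRNA")
  ref <- urna_reference(expr_tbl(um), st)
  expect_true(all(abs(ref$reference - true) < 4 * sigma / sqrt(n)))
})

test_that("the sample-quality filter calibrates the housekeeping stump optimally", {
  withr::with_seed(9, {
    n_genes <- 30; n <- 40
    base <- rnorm(n_genes, 8, 2)
    m <- sapply(seq_len(n), function(i) base + rnorm(n_genes, 0, 0.3))
    low <- 1:6
    for (s in low) m[, s] <- sample(m[, s])          # scrambled profiles
    hk <- 22:30
    m[hk, low] <- m[hk, low] - 5                     # depressed housekeeping
  })
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  expr <- expr_tbl(pmax(m, 0))
  reference <- tibble::tibble(gene_id = rownames(m), reference = base)
  hk_genes <- rownames(m)[hk]
  rep <- sample_quality_filter(expr_tbl(pmax(m, 0)), reference, hk_genes)
  expect_false(any(rep$quality_pass[low]))
  expect_true(all(rep$quality_pass[-low]))
  # separable housekeeping means -> stump misclassifies nobody
  expect_equal(rep$final_pass, rep$quality_pass)
  # matches an exhaustive search over every possible cut
  hk_mean <- colMeans(pmax(m, 0)[hk, ])
  grid <- sort(unique(c(hk_mean - 1e-9, hk_mean + 1e-9)))
  errs <- sapply(grid, function(t) sum(!rep$quality_pass & hk_mean >= t) +
                   sum(rep$quality_pass & hk_mean < t))
  t_star <- attr(rep, "housekeeping_threshold")
  err_star <- sum(!rep$quality_pass & hk_mean >= t_star) + sum(rep$quality_pass & hk_mean < t_star)
  expect_equal(err_star, min(errs))

  # perfect and anti correlation with the reference
  ref2 <- tibble::tibble(gene_id = c(sprintf("h%d", 1:9), "x1", "x2"),
                         reference = c(1:9, 10, 11))
  m2 <- cbind(good = ref2$reference, badx = rev(ref2$reference))
  rownames(m2) <- ref2$gene_id
  rep2 <- sample_quality_filter(expr_tbl(m2), ref2, sprintf("h%d", 1:9))
  expect_equal(rep2$urna_corr, c(1, -1), tolerance = 1e-12)
  expect_equal(rep2$quality_pass, c(TRUE, FALSE))

  expect_error(sample_quality_filter(expr_tbl(m2), ref2, c("h1", "h2")),
               "expected 9 housekeeping genes")
})

test_that("rerunning the chain on passing samples removes nothing", {
  co <- generate_cohort(small_config(seed = 91, planted_fail_read_count = 2L,
                                     planted_fail_low_quality = 9L))
  qc1 <- suppressMessages(run_qc(co$counts, co$samples))
  keep <- qc1$report$sample_id[qc1$report$final_pass]
  counts2 <- dplyr::bind_cols(co$counts[1:3], co$counts[, keep])
  qc2 <- suppressMessages(run_qc(counts2, co$samples))
  expect_true(all(qc2$report$final_pass))
})

test_that("with zero background the chain is invariant to rescaling a sample's counts", {
  co <- generate_cohort(small_config(seed = 95, background_mean = 0))
  qc1 <- suppressMessages(run_qc(co$counts, co$samples))
  counts2 <- co$counts
  counts2[[5]] <- counts2[[5]] * 3L   # sample column (stays above the read filter)
  qc2 <- suppressMessages(run_qc(counts2, co$samples))
  expect_equal(qc2$expr, qc1$expr, tolerance = 1e-12)
})
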