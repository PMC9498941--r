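test_that("z-scores standardize per gene over the declared universe", {
  x <- expr_tbl(matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("s1", "s2", "s3"))))
  z <- zscore(x)
  expect_equal(unlist(z[1, -1], use.names = FALSE), c(-1, 0, 1))  # sample SD = 1

  # constant genes: all-zero row, flagged
  y <- expr_tbl(rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5)) |>
                  `colnames<-`(c("s1", "s2", "s3")))
  zy <- zscore(y)
  expect_equal(unlist(zy[2, -1], use.names = FALSE), c(0, 0, 0))
  expect_equal(attr(zy, "degenerate_genes"), "g2")

  # samples outside the universe use the universe's mean/sd
  zu <- zscore(x, universe = c("s1", "s2"))
  mu <- 1.5; sdv <- sd(c(1, 2))
  expect_equal(zu$s3, (3 - mu) / sdv)

  expect_error(zscore(x, universe = "s1"), ">= 2 samples")
  expect_error(zscore(x, universe = c("s1", "nope")), "absent")
})

test_that("z-scores are calibrated and shift invariant on random matrices", {
  x <- random_expr(50, 30, seed = 101)
  z <- zscore(x)
  m <- as.matrix(z[, -1])
  expect_lt(max(abs(rowMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 1, sd) - 1)), 1e-9)

  # adding a constant to every sample's value of one gene leaves z unchanged
  x2 <- x
  x2[7, -1] <- x2[7, -1] + 5
  expect_equal(as.matrix(zscore(x2)[, -1]), m, tolerance = 1e-9)
})

test_that("signature scores are signed means of z and linear in signature union", {
  z <- expr_tbl(rbind(g1 = c(1, -1), g2 = c(-1, 1), g3 = c(0.5, 0.25)) |>
                  `colnames<-`(c("s1", "s2")))
  expect_equal(signature_score(z, signature_set("A", high = "g1"))$score, c(1, -1))
  s <- signature_score(z, signature_set("B", high = "g1", low = "g2"))
  expect_equal(s$score, c(1, -1))  # (z1 + (-z2))/2 = (1+1)/2, (-1-1)/2

  # loop oracle on a random 20-gene signature
  zr <- zscore(random_expr(60, 25, seed = 111))
  genes <- zr$gene_id
  withr::with_seed(112, {
    hi <- sample(genes, 12); lo <- sample(setdiff(genes, hi), 8)
  })
  got <- signature_score(zr, signature_set("S", high = hi, low = lo))$score
  zm <- as.matrix(zr[, -1]); rownames(zm) <- genes
  want <- sapply(colnames(zm), function(s) {
    acc <- 0
    for (g in hi) acc <- acc + zm[g, s]
    for (g in lo) acc <- acc - zm[g, s]
    acc / (length(hi) + length(lo))
  })
  expect_equal(got, unname(want), tolerance = 1e-12)

  # linearity: disjoint union scores are size-weighted means
  a <- signature_set("a", high = hi)
  b <- signature_set("b", low = lo)
  u <- signature_set("u", high = hi, low = lo)
  sa <- signature_score(zr, a)$score; sb <- signature_score(zr, b)$score
  su <- signature_score(zr, u)$score
  expect_equal(su, (12 * sa + 8 * sb) / 20, tolerance = 1e-12)

  # absent genes are skipped; fully absent signatures error
  expect_message(signature_score(zr, signature_set("m", high = c(hi, "ZZZ"))), "skipping")
  expect_error(signature_score(zr, signature_set("none", high = "ZZZ")), "no genes")
})

test_that("the vectorized Welch test agrees with stats::t.test", {
  withr::with_seed(121, {
    x <- matrix(rnorm(10 * 8, 5), 10, 8)
    y <- matrix(rnorm(10 * 12, 6, 2), 10, 12)
  })
  got <- oncopanel:::welch_rows(x, y)
  for (i in c(1, 4, 10)) {
    ref <- t.test(x[i, ], y[i, ])
    expect_equal(got$statistic[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df[i], unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p_value[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("marker selection recovers planted markers with correct directions", {
  cfg <- cohort_config(
    n_genes = 200,
    groups = tibble::tibble(group = c("A", "B"), n_samples = c(30L, 30L),
                            marker_genes = list(1:10, 11:20),
                            marker_log2fc = list(c(rep(2, 5), rep(-2, 5)), 2)),
    n_normal_samples = 6, n_urna_controls = 3,
    amplicon_genes = 101:108, amplicon_prevalence = 0, hscore_genes = integer(0),
    seed = 131
  )
  co <- generate_cohort(cfg)
  qc <- suppressMessages(run_qc(co$counts, co$samples))
  fit <- select_markers(qc$expr_pass, co$samples, "A", p_threshold = 0.005)
  st <- tidy(fit)
  planted_high <- sprintf("G%04d", 1:5)
  planted_low <- sprintf("G%04d", 6:10)
  expect_true(all(st$selected[st$gene_id %in% c(planted_high, planted_low)]))
  expect_true(all(st$direction[st$gene_id %in% planted_high] == "high"))
  expect_true(all(st$direction[st$gene_id %in% planted_low] == "low"))
  g <- glance(fit)
  expect_equal(g$n_target, 30)
  sig <- as_signature_set(fit)
  expect_true(all(planted_high %in% sig$high))
  expect_true(all(planted_low %in% sig$low))

  # comparator including normals changes the comparator size
  fit2 <- select_markers(qc$expr_pass, co$samples, "A",
                         comparator = "other_subtypes_plus_normal")
  expect_equal(fit2$n_comparator, fit$n_comparator + 6)

  # wilcoxon option runs and agrees on the planted markers
  fitw <- select_markers(qc$expr_pass, co$samples, "A", p_threshold = 0.005,
                         test = "wilcoxon")
  stw <- tidy(fitw)
  expect_true(all(stw$selected[stw$gene_id %in% planted_high]))
})

test_that("marker selection at level alpha is calibrated on null data", {
  # iid normal expression, no group structure: exact t null
  x <- random_expr(1000, 30, seed = 141)
  samples <- tibble::tibble(sample_id = sprintf("s%03d", 1:30),
                            sample_role = "tumor",
                            group = rep(c("A", "B"), each = 15))
  fit <- select_markers(x, samples, "A", p_threshold = 0.05)
  frac <- mean(tidy(fit)$selected)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("argmax subtype assignment breaks exact ties lexicographically", {
  z <- expr_tbl(rbind(g1 = c(0.5, 0.3), g2 = c(0.2, 0.3)) |>
                  `colnames<-`(c("s1", "s2")))
  calls <- assign_subtypes(z, list(signature_set("B", high = "g2"),
                                   signature_set("A", high = "g1")))
  expect_equal(calls$assigned_subtype, c("A", "A"))  # s2 ties 0.3/0.3 -> A
  expect_equal(calls$margin, c(0.3, 0))
  expect_equal(calls$tie_flag, c(FALSE, TRUE))

  expect_error(assign_subtypes(z, list(signature_set("A", high = "g1"))), ">= 2 signatures")
})

test_that("subtype assignment is invariant to signature list order", {
  zr <- zscore(random_expr(40, 15, seed = 151))
  sigs <- list(
    signature_set("S1", high = zr$gene_id[1:5]),
    signature_set("S2", high = zr$gene_id[6:10], low = zr$gene_id[11:12]),
    signature_set("S3", low = zr$gene_id[13:20])
  )
  c1 <- assign_subtypes(zr, sigs)
  c2 <- assign_subtypes(zr, rev(sigs))
  expect_equal(c1$assigned_subtype, c2$assigned_subtype)
  expect_equal(c1$margin, c2$margin)
})

test_that("reannotation cross-tabulates pathology against molecular calls", {
  calls <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                          assigned_subtype = c("A", "A", "B", "B"),
                          margin = c(0.5, 0.04, 0.5, 0.5))
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                            sample_role = "tumor",
                            group = c("A", "A", "B", "B"))
  re <- reannotate(calls, samples)
  expect_equal(re$crosstab$A, c(2L, 0L))
  expect_equal(re$crosstab$B, c(0L, 2L))
  expect_equal(sum(re$reassignments$moved), 0)
  expect_equal(sum(re$reassignments$weak), 1)

  samples2 <- samples; samples2$group[2] <- "B"   # one sample moved B -> A
  re2 <- reannotate(calls, samples2)
  expect_equal(sum(re2$reassignments$moved), 1)
  expect_equal(re2$crosstab$A[re2$crosstab$pathology == "B"], 1L)

  expect_error(reannotate(calls, samples[1:2, ]), "absent from the metadata")
})
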