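test_that("gene signal change measures the mean window difference", {
  withr::with_seed(5, {
    vals <- as.numeric(rpois(1000, 4))
  })
  ctrl <- coverage_track(list(chr1 = vals), 10, c(chr1 = 1e4),
                         state = "subtracted")
  kd <- ctrl
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(4000, 6000), end = c(4500, 6800),
                          strand = c("+", "-"), tss = c(4000, 6799))
  expect_true(all(gene_signal_change(kd, ctrl, genes)$delta == 0))

  kd5 <- ctrl
  kd5$values$chr1 <- ctrl$values$chr1 + 5
  res <- gene_signal_change(kd5, ctrl, genes, window = 2000)
  expect_equal(res$delta, c(5, 5))
  body <- gene_signal_change(kd5, ctrl, genes, region = "gene_body")
  expect_equal(body$delta, c(5, 5))

  # bin-aligned window equals a brute-force per-bin mean
  kd_r <- ctrl
  withr::with_seed(6, {
    kd_r$values$chr1 <- ctrl$values$chr1 + rnorm(1000)
  })
  res <- gene_signal_change(kd_r, ctrl, genes[1, ], window = 2000)
  idx <- (4000 - 2000) / 10 + seq_len(400)
  expect_equal(res$delta,
               mean(kd_r$values$chr1[idx]) - mean(ctrl$values$chr1[idx]))

  # a window past the chromosome start skips the gene with a log entry
  edge <- tibble::tibble(gene_id = "edge", chrom = "chr1", start = 100,
                         end = 600, strand = "+", tss = 100)
  expect_message(out <- gene_signal_change(kd5, ctrl, edge, window = 2000),
                 "skipped")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "skipped"), "edge")
})

test_that("rank correlation matches the naive average-rank oracle", {
  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman_cor(c(1, 1, 2, 3), c(2, 1, 4, 3))$rho,
               oracle_spearman_rho(c(1, 1, 2, 3), c(2, 1, 4, 3)),
               tolerance = 1e-12)
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      x <- sample(round(rnorm(n), sample(0:2, 1)))  # induces ties
      y <- round(rnorm(n), 1)
      expect_equal(spearman_cor(x, y)$rho, oracle_spearman_rho(x, y),
                   tolerance = 1e-12)
      # symmetry and monotone-transform invariance
      expect_equal(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
      expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
    }
  })
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)),
               class = "cx_constant_input")
  expect_error(spearman_cor(1:2, 1:2), class = "cx_validation_error")
})

test_that("exact permutation p-values match full enumeration for small n", {
  withr::with_seed(14, {
    for (i in 1:12) {
      n <- sample(3:7, 1)
      x <- rnorm(n)
      y <- if (i %% 3 == 0) round(rnorm(n)) else rnorm(n)  # some ties
      res <- spearman_cor(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, oracle_spearman_exact_p(x, y),
                   tolerance = 1e-12)
    }
  })
  # perfect monotone relation on distinct values: p = 2 / n!
  res <- spearman_cor(1:5, c(2, 4, 6, 8, 10))
  expect_equal(res$p_value, 2 / factorial(5))
  # large-n approximation agrees closely with the t reference
  withr::with_seed(15, {
    x <- rnorm(60); y <- x + rnorm(60)
  })
  res <- spearman_cor(x, y)
  expect_equal(res$method, "t-approximation")
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 0.05 * ref$p.value + 1e-8)
})

test_that("per-class correlation applies the fold-change filter and rules", {
  # constructed fixture: within the filtered subset (|log2fc| >= 1) the
  # coupling is perfectly monotone; the unfiltered set scrambles it
  de <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    log2fc = c(-3, -2.5, -2, -1.5, 2, 2.5, 0.3, -0.4, 0.1, 0.6, -0.2, 0.5),
    p_value = 0.01
  )
  delta <- c(-6, -5, -4, -3, 4, 5, 3.5, 4.5, -5.5, 1, 2, -1)
  changes <- tibble::tibble(gene_id = de$gene_id, mark = "H3K4me3",
                            region = "tss_window", delta = delta)
  labels <- tibble::tibble(gene_id = de$gene_id, class = "X1")
  filt <- correlate_by_class(de, changes, labels,
                             fc_filter = "abs_log2fc_ge_1")
  unfilt <- correlate_by_class(de, changes, labels, fc_filter = "none")
  expect_equal(filt$n, 6)
  expect_equal(filt$rho, 1)
  expect_lt(unfilt$rho, filt$rho)
  expect_equal(filt$filter, "abs_log2fc_ge_1")

  # too-small classes yield an undefined rho with a reason code
  small <- correlate_by_class(de[1:2, ], changes[1:2, ], labels[1:2, ])
  expect_true(is.na(small$rho))
  expect_equal(small$reason, "n_lt_3")

  # genes missing from the DE table are excluded and counted
  expect_message(
    res <- correlate_by_class(de[1:10, ], changes, labels),
    "excluded"
  )
  expect_equal(attr(res, "n_unjoined"), 2)
  expect_equal(res$n, 10)
})
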