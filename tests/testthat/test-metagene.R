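step_track <- function(seed = 2, chrom_len = 1e4, bin_size = 10) {
  withr::with_seed(seed, {
    vals <- list(chr1 = as.numeric(rpois(chrom_len / bin_size, 5)))
  })
  coverage_track(vals, bin_size, c(chr1 = chrom_len), state = "scaled")
}

gene_row <- function(gene_id, tss, strand, len = 500) {
  start <- if (strand == "+") tss else tss - len + 1
  tibble::tibble(gene_id = gene_id, chrom = "chr1", start = start,
                 end = start + len, strand = strand, tss = tss)
}

test_that("a constant track yields constant rows equal to the constant", {
  track <- constant_track(3.5)
  genes <- dplyr::bind_rows(gene_row("a", 5000, "+"), gene_row("b", 5000, "-"))
  pm <- tss_profile_matrix(track, genes, flank = 2000)
  expect_true(all(unclass(pm) == 3.5))
  expect_equal(dim(pm), c(2, 400))
})

test_that("genes without a full window are dropped and recorded", {
  track <- step_track()
  genes <- dplyr::bind_rows(gene_row("edge", 500, "+"),
                            gene_row("ok", 5000, "+"))
  expect_message(pm <- tss_profile_matrix(track, genes, flank = 2000),
                 "dropped")
  expect_equal(rownames(pm), "ok")
  expect_equal(attr(pm, "dropped"), "edge")
  expect_error(tss_profile_matrix(track, genes, flank = 1995),
               class = "cx_validation_error")
})

test_that("minus-strand rows are the exact reversal of plus-strand extraction", {
  track <- step_track(seed = 4)
  plus <- gene_row("p", 5003, "+")
  minus <- dplyr::mutate(plus, gene_id = "m", strand = "-")
  pm <- tss_profile_matrix(track, dplyr::bind_rows(plus, minus),
                           flank = 1000)
  expect_equal(unname(unclass(pm)["m", ]), rev(unclass(pm)["p", ]))
  # flip involution: flipping twice restores the row
  pm_flip <- tss_profile_matrix(track, dplyr::mutate(minus, strand = "+"),
                                flank = 1000)
  expect_equal(unname(unclass(pm_flip)[1, ]), rev(unclass(pm)["m", ]))
})

test_that("extraction equals a per-bp brute-force slice at bin size 1", {
  withr::with_seed(9, {
    vals <- as.numeric(rpois(4000, 3))
  })
  track <- coverage_track(list(chr1 = vals), 1, c(chr1 = 4000),
                          state = "scaled")
  genes <- dplyr::bind_rows(
    purrr::map(seq(600, 3200, length.out = 8), function(tss) {
      gene_row(sprintf("g%d", round(tss)), round(tss),
               sample(c("+", "-"), 1), len = 100)
    })
  )
  pm <- tss_profile_matrix(track, genes, flank = 500)
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    expected <- vals[(tss - 500):(tss + 499) + 1]
    if (genes$strand[i] == "-") expected <- rev(expected)
    expect_equal(unname(unclass(pm)[genes$gene_id[i], ]), expected)
  }
})

test_that("aggregation gives per-class means, population SD and counts", {
  track <- constant_track(2)
  genes <- dplyr::bind_rows(gene_row("a", 4000, "+"), gene_row("b", 6000, "+"),
                            gene_row("c", 5000, "-"))
  pm <- tss_profile_matrix(track, genes, flank = 1000)
  labels <- tibble::tibble(gene_id = c("a", "b", "c"),
                           class = c("X1", "X1", "X2"))
  mg <- metagene_aggregate(pm, labels)
  expect_s3_class(mg, "metagene_profile")
  expect_true(all(mg$sd == 0))      # identical rows -> zero dispersion
  expect_true(all(mg$mean == 2))
  expect_equal(unique(mg$n[mg$class == "X1"]), 2)

  # linearity: scaling the track scales every class mean
  track4 <- constant_track(8)
  mg4 <- metagene_aggregate(tss_profile_matrix(track4, genes, flank = 1000),
                            labels)
  expect_equal(mg4$mean, 4 * mg$mean)

  expect_warning(
    metagene_aggregate(pm, dplyr::bind_rows(
      labels, tibble::tibble(gene_id = "zz", class = "Xins"))),
    "omitted"
  )
  expect_error(metagene_aggregate(pm, labels[1:2, ]),
               class = "cx_validation_error")
})

test_that("planted TSS enrichment peaks at the center bin of the class mean", {
  cfg <- simulation_config(seed = 31, n_genes = 200, chrom_len = 1.2e6,
                           spike_chrom_len = 2e5, n_fragments = 6e4,
                           n_de_up = 20, n_de_down = 20)
  gen <- simulate_genomes(cfg)
  truth <- simulate_truth(cfg, gen$genes)
  frags <- simulate_chip_sample(cfg, gen$genes, truth, "H3K4me3", "control")
  part <- partition_fragments(frags, gen$space)
  cov <- scale_track(fragment_coverage(part$target, gen$space),
                     spike_scale_factor(part$counts[["n_spike"]]))
  pm <- tss_profile_matrix(cov, gen$genes, flank = 2000)
  labels <- dplyr::select(truth$genes, gene_id, class)
  mg <- metagene_aggregate(pm, labels)
  center <- which(attr(pm, "positions") == 0)
  for (cl in c("X1", "X2")) {
    prof <- mg$mean[mg$class == cl]
    expect_lte(abs(which.max(prof) - center), 1)
  }
})

test_that("log2-ratio profiles behave at the identity and scaling limits", {
  track <- constant_track(10)
  genes <- dplyr::bind_rows(gene_row("a", 4000, "+"), gene_row("b", 6000, "-"))
  labels <- tibble::tibble(gene_id = c("a", "b"), class = "X1")
  mg <- metagene_aggregate(tss_profile_matrix(track, genes, flank = 1000),
                           labels)
  expect_true(all(log2_ratio_profile(mg, mg)$log2_ratio == 0))

  double <- metagene_aggregate(
    tss_profile_matrix(constant_track(20), genes, flank = 1000), labels)
  ratio <- log2_ratio_profile(double, mg, pseudocount = 1e-6)
  expect_equal(ratio$log2_ratio, rep(1, nrow(ratio)), tolerance = 1e-6)

  short <- mg[mg$position < 0, ]
  expect_error(log2_ratio_profile(short, mg), class = "cx_validation_error")
})
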