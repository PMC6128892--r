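toy_space <- genome_space(c(chr1 = 1e4, spike_chr1 = 5e3))

toy_frags <- function(n_target, n_spike, seed = 1) {
  withr::with_seed(seed, {
    start_t <- sample.int(9800, n_target, replace = TRUE) - 1
    start_s <- sample.int(4800, n_spike, replace = TRUE) - 1
    tibble::tibble(
      chrom = c(rep("chr1", n_target), rep("spike_chr1", n_spike)),
      start = c(start_t, start_s), end = c(start_t, start_s) + 200,
      strand = "+"
    )
  })
}

test_that("partition preserves counts and splits purely by namespace", {
  frags <- toy_frags(850, 150)
  part <- partition_fragments(frags, toy_space)
  expect_equal(unname(part$counts), c(850, 150))
  expect_equal(sum(part$counts), nrow(frags))
  expect_true(all(part$target$chrom == "chr1"))
  expect_true(all(startsWith(part$spike$chrom, "spike_")))

  only_target <- toy_frags(10, 0)
  expect_equal(partition_fragments(only_target, toy_space)$counts[["n_spike"]], 0)

  bad <- tibble::tibble(chrom = "chrUn", start = 0, end = 100, strand = "+")
  expect_error(partition_fragments(bad, toy_space), "chrUn",
               class = "cx_validation_error")
})

test_that("deduplication keeps one representative per coordinate tuple", {
  f <- tibble::tibble(
    chrom = "chr1", start = c(10, 10, 10, 10), end = c(210, 210, 210, 210),
    strand = c("+", "+", "+", "-")
  )
  d <- deduplicate_fragments(f)
  expect_equal(nrow(d), 2)        # strand is part of the key
  expect_identical(deduplicate_fragments(d), d)  # idempotent
})

test_that("scale factors implement reference-count normalization", {
  expect_equal(spike_scale_factor(1e6)$alpha, 1)
  expect_equal(spike_scale_factor(150000)$alpha, 1e6 / 150000)
  expect_equal(spike_scale_factor(150000)$alpha, 6.6667, tolerance = 1e-4)
  expect_error(spike_scale_factor(0), class = "cx_validation_error")
  # equal spike counts across conditions mean equal alphas
  expect_equal(spike_scale_factor(2e5)$alpha, spike_scale_factor(2e5)$alpha)
  expect_equal(library_size_factor(5e5)$alpha, 2)
})

test_that("binned coverage counts overlaps, matching a brute-force scan", {
  one <- tibble::tibble(chrom = "chr1", start = 100, end = 300, strand = "+")
  cov <- fragment_coverage(one, toy_space, bin_size = 10)
  expect_equal(sum(cov$values$chr1 > 0), 20)
  expect_equal(sum(cov$values$chr1), 20)

  empty <- toy_frags(0, 0)
  cov0 <- fragment_coverage(empty, toy_space, bin_size = 10,
                            chroms = "chr1")
  expect_true(all(cov0$values$chr1 == 0))

  frags <- toy_frags(1000, 0, seed = 3)
  cov <- fragment_coverage(frags, toy_space, bin_size = 10)
  expect_equal(cov$values$chr1, oracle_coverage(frags, 1e4, 10))
  # partial final bin: bin grid still covers the chromosome exactly
  odd_space <- genome_space(c(chr1 = 9995, spike_chr1 = 100))
  frags2 <- dplyr::filter(frags, end <= 9995)
  cov2 <- fragment_coverage(frags2, odd_space, bin_size = 10)
  expect_equal(cov2$values$chr1, oracle_coverage(frags2, 9995, 10))
})

test_that("normalize_subtract applies alphas bin-wise and is linear", {
  chip <- coverage_track(list(chr1 = c(8, 4, 0)), 10, c(chr1 = 30))
  input <- coverage_track(list(chr1 = c(3, 1, 2)), 10, c(chr1 = 30))
  sub <- normalize_subtract(chip, input,
                            new_sf <- library_size_factor(5e5),  # alpha 2
                            spike_scale_factor(1e6))             # alpha 1
  expect_equal(sub$values$chr1, c(13, 7, -2))
  expect_equal(sub$state, "subtracted")

  clipped <- normalize_subtract(chip, input, new_sf, spike_scale_factor(1e6),
                                clip_negative = TRUE)
  expect_equal(clipped$values$chr1, c(13, 7, 0))

  # self-subtraction with equal alphas is exactly zero
  self <- normalize_subtract(chip, chip, spike_scale_factor(5),
                             spike_scale_factor(5))
  expect_true(all(self$values$chr1 == 0))

  # linearity in the chip track: doubling chip doubles (chip-part of) output
  chip2 <- coverage_track(list(chr1 = c(16, 8, 0)), 10, c(chr1 = 30))
  zero <- coverage_track(list(chr1 = c(0, 0, 0)), 10, c(chr1 = 30))
  a <- normalize_subtract(chip, zero, new_sf, spike_scale_factor(1e6))
  b <- normalize_subtract(chip2, zero, new_sf, spike_scale_factor(1e6))
  expect_equal(b$values$chr1, 2 * a$values$chr1)

  short <- coverage_track(list(chr1 = c(1, 2)), 10, c(chr1 = 20))
  expect_error(normalize_subtract(chip, short, new_sf, new_sf),
               class = "cx_validation_error")
})

test_that("track utilities average replicates and summarise signal", {
  t1 <- coverage_track(list(chr1 = c(2, 4)), 10, c(chr1 = 20))
  t2 <- coverage_track(list(chr1 = c(4, 8)), 10, c(chr1 = 20))
  avg <- average_tracks(list(t1, t2))
  expect_equal(avg$values$chr1, c(3, 6))
  expect_equal(track_mean(avg), 4.5)
  tidied <- tidy(t1)
  expect_equal(tidied$value, c(2, 4))
  expect_equal(tidied$end, c(10, 20))
})
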