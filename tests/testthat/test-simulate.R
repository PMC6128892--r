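test_that("gene placement tiles the target chromosome with alternating strands", {
  cfg <- tiny_sim_config()
  gen <- simulate_genomes(cfg)
  genes <- gen$genes
  expect_equal(nrow(genes), 40)
  expect_equal(sum(genes$strand == "+"), 20)
  expect_true(all(genes$start[-1] >= genes$end[-nrow(genes)]))
  expect_true(all(genes$tss - cfg$flank >= 0))
  expect_true(all(genes$tss + cfg$flank <= cfg$chrom_len))
  expect_equal(spike_chroms(gen$space), "spike_chr1")

  expect_error(simulate_genomes(simulation_config(n_genes = 0)),
               class = "cx_validation_error")
  expect_error(
    simulate_genomes(simulation_config(n_genes = 100, chrom_len = 1e5)),
    class = "cx_sizing_error"
  )
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_experiment(tiny_sim_config(seed = 3))
  b <- simulate_experiment(tiny_sim_config(seed = 3))
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$de_table, b$de_table)
  c <- simulate_experiment(tiny_sim_config(seed = 4))
  expect_false(identical(a$fragments, c$fragments))
})

test_that("expression profiles respect the planted class construction", {
  cfg <- tiny_sim_config(seed = 5)
  gen <- simulate_genomes(cfg)
  truth <- simulate_truth(cfg, gen$genes)
  prof <- simulate_expression_profiles(cfg, gen$genes, truth)
  props <- as.matrix(prof[, c("prop_X1", "prop_X2", "prop_Xins")])
  expect_equal(rowSums(props), rep(1, nrow(props)), tolerance = 1e-9)
  for (cl in c("X1", "X2", "Xins")) {
    rows <- truth$genes$class == cl
    expect_true(all(props[rows, paste0("prop_", cl)] > 0.5))
  }
  expect_true(all(props[truth$genes$class == "none", ] < 0.5))
})

test_that("planted DE genes sit beyond both thresholds and others fail one", {
  cfg <- tiny_sim_config(seed = 6)
  gen <- simulate_genomes(cfg)
  truth <- simulate_truth(cfg, gen$genes)
  g <- truth$genes
  b <- log2(1.5)
  expect_equal(sum(g$de_status == "up"), 4)
  expect_equal(sum(g$de_status == "down"), 4)
  expect_true(all(g$log2fc[g$de_status == "up"] >= b))
  expect_true(all(g$p_value[g$de_status != "unchanged"] < 0.05))
  expect_true(all(abs(g$log2fc[g$de_status == "unchanged"]) < b))
  expect_true(all(g$p_value[g$de_status == "unchanged"] >= 0.05))
})

test_that("spike-in yield is condition-invariant while target yield shifts", {
  cfg <- simulation_config(seed = 9, n_genes = 100, chrom_len = 1e6,
                           spike_chrom_len = 2e5, n_fragments = 1e5,
                           n_de_up = 10, n_de_down = 10,
                           global_chip_shift = 2)
  gen <- simulate_genomes(cfg)
  truth <- simulate_truth(cfg, gen$genes)
  ctrl <- simulate_chip_sample(cfg, gen$genes, truth, "H3K4me3", "control")
  kd <- simulate_chip_sample(cfg, gen$genes, truth, "H3K4me3", "knockdown")
  n_spike <- function(f) sum(startsWith(f$chrom, "spike_"))
  n_target <- function(f) sum(!startsWith(f$chrom, "spike_"))
  # spike counts agree within Poisson noise; target:spike ratio doubles
  expect_equal(n_spike(kd) / n_spike(ctrl), 1, tolerance = 0.05)
  expect_equal((n_target(kd) / n_spike(kd)) /
                 (n_target(ctrl) / n_spike(ctrl)), 2, tolerance = 0.1)
  # control spike yield is close to the configured fraction of the library
  expect_equal(n_spike(ctrl) / cfg$n_fragments, 0.15, tolerance = 0.05)
  expect_error(
    simulate_chip_sample(cfg, gen$genes, truth, "H3K9me3", "control"),
    class = "cx_validation_error"
  )
})

test_that("input samples show no TSS peak (flat coverage across TSS bins)", {
  cfg <- simulation_config(seed = 10, n_genes = 100, chrom_len = 1e6,
                           spike_chrom_len = 2e5, n_fragments = 1e5,
                           n_de_up = 10, n_de_down = 10)
  gen <- simulate_genomes(cfg)
  truth <- simulate_truth(cfg, gen$genes)
  input <- simulate_chip_sample(cfg, gen$genes, truth, "input", "control")
  part <- partition_fragments(input, gen$space)
  cov <- scale_track(fragment_coverage(part$target, gen$space),
                     spike_scale_factor(part$counts[["n_spike"]]))
  pm <- tss_profile_matrix(cov, gen$genes, flank = 2000)
  prof <- colMeans(unclass(pm))
  fit <- stats::lm(prof ~ attr(pm, "positions"))
  # slope across the 4 kb window is a negligible share of the mean level
  expect_lt(abs(stats::coef(fit)[2]) * 4000, 0.05 * mean(prof))
  chip <- simulate_chip_sample(cfg, gen$genes, truth, "H3K4me3", "control")
  part_c <- partition_fragments(chip, gen$space)
  cov_c <- scale_track(fragment_coverage(part_c$target, gen$space),
                       spike_scale_factor(part_c$counts[["n_spike"]]))
  pm_c <- tss_profile_matrix(cov_c, gen$genes, flank = 2000)
  # by contrast, a real mark is strongly peaked at the TSS
  expect_gt(max(colMeans(unclass(pm_c))), 2 * min(colMeans(unclass(pm_c))))
})

test_that("a configured duplication rate re-emits fragments verbatim", {
  cfg <- tiny_sim_config(seed = 12, duplication_rate = 0.2)
  sim_frags <- simulate_chip_sample(
    cfg, simulate_genomes(cfg)$genes,
    simulate_truth(cfg, simulate_genomes(cfg)$genes), "input", "control"
  )
  dedup <- deduplicate_fragments(sim_frags)
  distinct_n <- nrow(dplyr::distinct(sim_frags, chrom, start, end, strand))
  expect_equal(nrow(dedup), distinct_n)
  expect_lt(nrow(dedup), nrow(sim_frags))
})
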