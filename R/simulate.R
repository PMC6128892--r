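#' Histone marks profiled by the pipeline
#' @export
CHIP_MARKS <- c("H3K4me3", "H3K4me1", "H3K27me3")

#' Configuration for the synthetic experiment generator
#'
#' Bundles every knob of the simulator that emulates the structure of a
#' spike-in ChIP-seq + FACS-compartment RNA-seq study: a target genome with
#' regularly spaced genes, an exogenous spike-in genome contributing roughly
#' 15% of each library, three histone marks plus input chromatin in two
#' conditions (control and knockdown), three compartment expression-
#' enrichment classes, ~5% of genes mis-regulated in each direction, and an
#' optional rank coupling between planted promoter-mark changes and planted
#' expression changes in one class.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of genes on the target chromosome.
#' @param gene_length Gene length in bp.
#' @param chrom_len,spike_chrom_len Target and spike-in chromosome lengths.
#' @param spike_fraction Expected fraction of each library drawn from the
#'   spike-in genome in the control condition (default 0.15).
#' @param global_chip_shift Multiplicative factor applied to the
#'   knockdown-condition target-genome fragment yield of every sample;
#'   spike-in yield is never shifted (the spike-in contract). 1 = no global
#'   change.
#' @param class_proportions Named fractions of genes assigned to the
#'   `X1`, `X2`, `Xins` and `none` expression classes (must sum to <= 1;
#'   any remainder goes to `none`).
#' @param n_de_up,n_de_down Planted numbers of up-/down-regulated genes.
#'   Defaults: 5% of `n_genes` each.
#' @param coupling_rho Target Spearman correlation between the planted
#'   TSS-proximal change of `coupling_mark` and the planted expression
#'   log2 fold change within `coupling_class` (0 disables coupling).
#' @param coupling_class,coupling_mark Class and mark carrying the coupling.
#' @param delta_scale Log-scale spread of the planted per-gene
#'   knockdown/control enrichment ratio for the coupled genes.
#' @param fragment_len Fragment length in bp (default 200).
#' @param n_fragments Expected background fragments per sample (target +
#'   spike-in; TSS-peak fragments come on top of this).
#' @param tss_sd Standard deviation (bp) of the Gaussian fragment-center
#'   distribution around each TSS (default 200, nucleosome-scale).
#' @param duplication_rate Fraction of fragments re-emitted verbatim to
#'   exercise deduplication (default 0).
#' @param flank Metagene flank (bp) genes are spaced to accommodate.
#' @param enrichment_base Marks x classes matrix of expected TSS-peak
#'   fragment counts per gene in the control condition.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42,
                              n_genes = 1000,
                              gene_length = 1000,
                              chrom_len = 6e6,
                              spike_chrom_len = 1e6,
                              spike_fraction = 0.15,
                              global_chip_shift = 1,
                              class_proportions = c(X1 = 0.3, X2 = 0.3,
                                                    Xins = 0.2, none = 0.2),
                              n_de_up = round(0.05 * n_genes),
                              n_de_down = round(0.05 * n_genes),
                              coupling_rho = -0.5,
                              coupling_class = "X1",
                              coupling_mark = "H3K4me1",
                              delta_scale = 0.8,
                              fragment_len = 200,
                              n_fragments = 1e5,
                              tss_sd = 200,
                              duplication_rate = 0,
                              flank = 2000,
                              enrichment_base = NULL) {
  check_scalar_number(seed, "seed")
  check_scalar_number(n_genes, "n_genes", min = 0)
  check_scalar_number(spike_fraction, "spike_fraction", min = 0, max = 1)
  check_scalar_number(global_chip_shift, "global_chip_shift", min = 0,
                      strict_min = TRUE)
  check_scalar_number(coupling_rho, "coupling_rho", min = -1, max = 1)
  check_scalar_number(duplication_rate, "duplication_rate", min = 0, max = 1)
  check_scalar_number(n_de_up, "n_de_up", min = 0)
  check_scalar_number(n_de_down, "n_de_down", min = 0)
  classes <- c("X1", "X2", "Xins", "none")
  if (!all(names(class_proportions) %in% classes)) {
    cx_abort("class_proportions must be named among X1, X2, Xins, none.",
             "cx_validation_error")
  }
  props <- setNames(numeric(4), classes)
  props[names(class_proportions)] <- class_proportions
  if (any(props < 0) || any(props > 1) || sum(props[1:3]) > 1 + 1e-9) {
    cx_abort("class_proportions must lie in [0,1] and sum to at most 1.",
             "cx_validation_error")
  }
  props["none"] <- max(props["none"], 1 - sum(props[1:3]))
  if (abs(sum(props) - 1) > 1e-9) {
    cx_abort("class_proportions (with 'none') must sum to 1.",
             "cx_validation_error")
  }
  if (n_de_up + n_de_down > n_genes) {
    cx_abort("n_de_up + n_de_down exceeds n_genes.", "cx_validation_error")
  }
  if (is.null(enrichment_base)) {
    enrichment_base <- rbind(
      H3K4me3 = c(X1 = 80, X2 = 40, Xins = 15, none = 8),
      H3K4me1 = c(X1 = 45, X2 = 35, Xins = 60, none = 20),
      H3K27me3 = c(X1 = 10, X2 = 25, Xins = 50, none = 30)
    )
  }
  if (!all(rownames(enrichment_base) == CHIP_MARKS) ||
      !all(colnames(enrichment_base) == classes) ||
      any(enrichment_base < 0)) {
    cx_abort("enrichment_base must be a non-negative marks x classes matrix.",
             "cx_validation_error")
  }
  if (!coupling_class %in% classes[1:3] ||
      !coupling_mark %in% CHIP_MARKS) {
    cx_abort("Unknown coupling_class or coupling_mark.",
             "cx_validation_error")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         gene_length = gene_length, chrom_len = chrom_len,
         spike_chrom_len = spike_chrom_len, spike_fraction = spike_fraction,
         global_chip_shift = global_chip_shift, class_proportions = props,
         n_de_up = as.integer(n_de_up), n_de_down = as.integer(n_de_down),
         coupling_rho = coupling_rho, coupling_class = coupling_class,
         coupling_mark = coupling_mark, delta_scale = delta_scale,
         fragment_len = fragment_len, n_fragments = n_fragments,
         tss_sd = tss_sd, duplication_rate = duplication_rate,
         flank = flank, enrichment_base = enrichment_base),
    class = "simulation_config"
  )
}

# Independent, collision-free RNG stream per generator stage, derived from
# the single user-facing seed.
with_sim_seed <- function(config, stream, code) {
  base <- (abs(config$seed) %% 20000000L) * 100L
  withr::with_seed(base + stream, code)
}

sim_stream_id <- function(mark, condition) {
  10L + 2L * (match(mark, c("input", CHIP_MARKS)) - 1L) +
    (condition == "knockdown")
}

#' Build the simulated genome space and gene annotation
#'
#' Genes tile the single target chromosome at regular spacing with
#' alternating strands; the spike-in chromosome carries no genes. Spacing
#' must leave at least a full metagene flank on both sides of every gene.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `space` ([genome_space()]) and `genes`
#'   (gene-model tibble as from [read_annotation()]).
#' @export
simulate_genomes <- function(config) {
  if (config$n_genes < 1L) {
    cx_abort("n_genes must be at least 1.", "cx_validation_error")
  }
  spacing <- floor(config$chrom_len / config$n_genes)
  if (spacing < config$gene_length + 2 * config$flank) {
    cx_abort(sprintf(
      "Chromosome of length %s is too short for %d genes with %s bp flanks.",
      format_bp(config$chrom_len), config$n_genes, format_bp(config$flank)
    ), "cx_sizing_error")
  }
  i <- seq_len(config$n_genes)
  start <- (i - 1) * spacing + floor((spacing - config$gene_length) / 2)
  end <- start + config$gene_length
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  genes <- tibble(
    gene_id = sprintf("gene_%05d", i),
    chrom = "chr1", start = start, end = end, strand = strand,
    tss = ifelse(strand == "+", start, end - 1)
  )
  space <- genome_space(c(chr1 = config$chrom_len,
                          spike_chr1 = config$spike_chrom_len))
  list(space = space, genes = genes)
}

#' Plant the ground truth of a simulated experiment
#'
#' Assigns expression classes, plants exactly `n_de_up` / `n_de_down`
#' differentially expressed genes with log2 fold changes beyond
#' `+/- log2(1.5)` and p-values below 0.05 (all other genes fail both
#' thresholds), and sets per-gene TSS-peak fragment rates per mark and
#' condition. Within `coupling_class`, the knockdown/control rate ratio of
#' `coupling_mark` is rank-coupled to the planted log2 fold change through a
#' Gaussian copula whose latent correlation `2*sin(pi*rho/6)` makes the
#' planted Spearman correlation equal `coupling_rho` in expectation.
#'
#' @param config A [simulation_config()].
#' @param genes Gene tibble from [simulate_genomes()].
#' @return An object of class `ground_truth`: list with `genes` (gene_id,
#'   class, de_status, log2fc, p_value), `enrichment` (gene_id, mark,
#'   condition, rate) and `sample_scale` (condition, target_scale).
#' @export
simulate_truth <- function(config, genes) {
  n <- nrow(genes)
  with_sim_seed(config, 1L, {
    classes <- assign_classes(config$class_proportions, n)
    # latent expression-change score z2 and mark-change score z1
    z2 <- rnorm(n)
    z1 <- rnorm(n)
    in_couple <- classes == config$coupling_class
    if (config$coupling_rho != 0 && any(in_couple)) {
      r <- 2 * sin(pi * config$coupling_rho / 6)
      z1[in_couple] <- r * z2[in_couple] +
        sqrt(1 - r^2) * rnorm(sum(in_couple))
    }
    de <- planted_log2fc(z2, config$n_de_up, config$n_de_down)
    p_value <- numeric(n)
    is_de <- de$status != "unchanged"
    p_value[is_de] <- runif(sum(is_de), 0, 0.05)
    p_value[!is_de] <- runif(sum(!is_de), 0.05, 1)
  })
  enrichment <- tidyr::expand_grid(
    gene_id = genes$gene_id, mark = CHIP_MARKS,
    condition = c("control", "knockdown")
  ) |>
    mutate(
      class = classes[match(.data$gene_id, genes$gene_id)],
      rate = config$enrichment_base[cbind(.data$mark, .data$class)]
    )
  couple <- enrichment$mark == config$coupling_mark &
    enrichment$condition == "knockdown" &
    enrichment$class == config$coupling_class
  if (any(couple)) {
    idx <- match(enrichment$gene_id[couple], genes$gene_id)
    enrichment$rate[couple] <- enrichment$rate[couple] *
      exp(config$delta_scale * z1[idx])
  }
  structure(
    list(
      genes = tibble(gene_id = genes$gene_id, class = classes,
                     de_status = de$status, log2fc = de$log2fc,
                     p_value = p_value),
      enrichment = select(enrichment, "gene_id", "mark", "condition", "rate"),
      sample_scale = tibble(condition = c("control", "knockdown"),
                            target_scale = c(1, config$global_chip_shift))
    ),
    class = "ground_truth"
  )
}

assign_classes <- function(props, n) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(names(props), times = base))
}

# Monotone map from the latent score to planted log2 fold changes:
# the lowest n_down ranks fall at or below -log2(1.5), the highest n_up at
# or above +log2(1.5), everything else strictly inside the open interval.
planted_log2fc <- function(z, n_up, n_down) {
  n <- length(z)
  s <- rank(z, ties.method = "first")
  b <- log2(1.5)
  span <- 2
  log2fc <- numeric(n)
  status <- rep("unchanged", n)
  down <- s <= n_down
  up <- s > n - n_up
  mid <- !down & !up
  if (n_down > 0) {
    log2fc[down] <- -b - (n_down - s[down] + 1) / n_down * span
    status[down] <- "down"
  }
  if (n_up > 0) {
    log2fc[up] <- b + (s[up] - (n - n_up)) / n_up * span
    status[up] <- "up"
  }
  if (any(mid)) {
    u <- (s[mid] - n_down) / (n - n_up - n_down + 1)
    log2fc[mid] <- (2 * u - 1) * 0.999 * b
  }
  list(log2fc = log2fc, status = status)
}

#' Simulate one ChIP or input sample as deduplicated fragments
#'
#' Background fragments are uniform over each genome; for the three histone
#' marks, additional fragments are drawn around each gene's TSS with Gaussian
#' centers (`tss_sd`) at the per-gene rate planted in the ground truth. In
#' the knockdown condition every target-genome yield (background and peaks,
#' input included) is multiplied by `global_chip_shift`, while spike-in yield
#' is left untouched — the contract that lets spike-in normalization recover
#' global shifts. A nonzero `duplication_rate` re-emits that fraction of
#' fragments verbatim.
#'
#' @param config A [simulation_config()].
#' @param genes Gene tibble from [simulate_genomes()].
#' @param truth A [simulate_truth()] result (ignored for `mark = "input"`).
#' @param mark One of `"H3K4me3"`, `"H3K4me1"`, `"H3K27me3"`, `"input"`.
#' @param condition `"control"` or `"knockdown"`.
#' @return A fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @export
simulate_chip_sample <- function(config, genes, truth, mark,
                                 condition = c("control", "knockdown")) {
  condition <- match.arg(condition)
  if (!mark %in% c(CHIP_MARKS, "input")) {
    cx_abort(sprintf("Unknown mark '%s'.", mark), "cx_validation_error")
  }
  shift <- if (condition == "knockdown") config$global_chip_shift else 1
  flen <- config$fragment_len
  with_sim_seed(config, sim_stream_id(mark, condition), {
    n_bg_target <- rpois(1, (1 - config$spike_fraction) * config$n_fragments *
                           shift)
    n_bg_spike <- rpois(1, config$spike_fraction * config$n_fragments)
    bg_target <- uniform_fragments("chr1", config$chrom_len, n_bg_target, flen)
    bg_spike <- uniform_fragments("spike_chr1", config$spike_chrom_len,
                                  n_bg_spike, flen)
    peaks <- NULL
    if (mark != "input") {
      rates <- truth$enrichment |>
        filter(.data$mark == !!mark, .data$condition == !!condition)
      rates <- rates$rate[match(genes$gene_id, rates$gene_id)]
      counts <- rpois(nrow(genes), rates * shift)
      idx <- rep.int(seq_len(nrow(genes)), counts)
      if (length(idx) > 0) {
        centers <- rnorm(length(idx), mean = genes$tss[idx], sd = config$tss_sd)
        start <- pmin(pmax(round(centers - flen / 2), 0),
                      config$chrom_len - flen)
        peaks <- tibble(chrom = "chr1", start = start, end = start + flen,
                        strand = sample(c("+", "-"), length(idx),
                                        replace = TRUE))
      }
    }
    frags <- bind_rows(bg_target, peaks, bg_spike)
    if (config$duplication_rate > 0 && nrow(frags) > 0) {
      n_dup <- round(config$duplication_rate * nrow(frags))
      frags <- bind_rows(frags,
                         frags[sample.int(nrow(frags), n_dup,
                                          replace = FALSE), ])
    }
    frags
  })
}

uniform_fragments <- function(chrom, len, n, flen) {
  if (n == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  strand = character()))
  }
  start <- floor(runif(n, 0, len - flen))
  tibble(chrom = chrom, start = start, end = start + flen,
         strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate proportional expression across FACS compartments
#'
#' For a gene of true class C, the C proportion is drawn uniformly in
#' (0.55, 0.95) and the remainder split at random between the other two
#' compartments; class `none` genes get three proportions all below 0.5.
#' Rows sum to 1 exactly.
#'
#' @inheritParams simulate_chip_sample
#' @return A tibble with `gene_id`, `prop_X1`, `prop_X2`, `prop_Xins`.
#' @export
simulate_expression_profiles <- function(config, genes, truth) {
  n <- nrow(genes)
  classes <- truth$genes$class[match(genes$gene_id, truth$genes$gene_id)]
  with_sim_seed(config, 2L, {
    props <- matrix(0, nrow = n, ncol = 3,
                    dimnames = list(NULL, c("X1", "X2", "Xins")))
    for (cl in c("X1", "X2", "Xins")) {
      rows <- which(classes == cl)
      if (length(rows) == 0) next
      main <- runif(length(rows), 0.55, 0.95)
      split <- runif(length(rows))
      others <- setdiff(c("X1", "X2", "Xins"), cl)
      props[rows, cl] <- main
      props[rows, others[1]] <- (1 - main) * split
      props[rows, others[2]] <- (1 - main) * (1 - split)
    }
    rows <- which(classes == "none")
    if (length(rows) > 0) {
      props[rows, ] <- balanced_proportions(length(rows))
    }
  })
  tibble(gene_id = genes$gene_id, prop_X1 = props[, "X1"],
         prop_X2 = props[, "X2"], prop_Xins = props[, "Xins"])
}

# Dirichlet(1,1,1) draws conditioned on max < 0.5 (rejection sampling)
balanced_proportions <- function(n) {
  out <- matrix(NA_real_, nrow = n, ncol = 3)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- matrix(stats::rexp(3 * length(todo)), ncol = 3)
    draw <- draw / rowSums(draw)
    ok <- apply(draw, 1, max) < 0.5
    out[todo[ok], ] <- draw[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  out
}

#' Materialize the simulated differential-expression table
#'
#' Emits the planted per-gene log2 fold change and p-value, mimicking a
#' differential-expression result table produced upstream (the DE model
#' itself is out of scope and consumed as data).
#'
#' @inheritParams simulate_chip_sample
#' @return A tibble with `gene_id`, `log2fc`, `p_value`.
#' @export
simulate_de_table <- function(config, genes, truth) {
  truth$genes |>
    select("gene_id", "log2fc", "p_value")
}

#' Run the full generator
#'
#' @param config A [simulation_config()].
#' @param marks Histone marks to simulate (input is always included).
#' @return A list of class `simulated_experiment` with `config`, `space`,
#'   `genes`, `truth`, `profiles`, `de_table` and `fragments` (a named list
#'   `<mark>_<condition>`).
#' @export
simulate_experiment <- function(config, marks = CHIP_MARKS) {
  gen <- simulate_genomes(config)
  truth <- simulate_truth(config, gen$genes)
  combos <- tidyr::expand_grid(mark = c("input", marks),
                               condition = c("control", "knockdown"))
  fragments <- purrr::pmap(combos, function(mark, condition) {
    simulate_chip_sample(config, gen$genes, truth, mark, condition)
  })
  names(fragments) <- paste(combos$mark, combos$condition, sep = "_")
  structure(
    list(config = config, space = gen$space, genes = gen$genes,
         truth = truth,
         profiles = simulate_expression_profiles(config, gen$genes, truth),
         de_table = simulate_de_table(config, gen$genes, truth),
         fragments = fragments),
    class = "simulated_experiment"
  )
}

#' Write a simulated experiment to disk in pipeline input formats
#'
#' Emits exactly the formats the readers consume (chromosome sizes TSV, gene
#' BED6, fragment BED6 per sample, expression-profile and DE TSVs) plus the
#' ground truth and the resolved configuration (YAML) for provenance.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frag_dir <- file.path(dir, "fragments")
  dir.create(frag_dir, showWarnings = FALSE)
  paths <- list(
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    annotation = file.path(dir, "genes.bed"),
    expression_profiles = file.path(dir, "expression_profiles.tsv"),
    de_table = file.path(dir, "de_table.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "config_resolved.yaml")
  )
  readr::write_tsv(
    tibble(names(sim$space$chrom_sizes),
           format_bp(sim$space$chrom_sizes)),
    paths$chrom_sizes, col_names = FALSE
  )
  write_annotation(sim$genes, paths$annotation, format = "bed")
  readr::write_tsv(sim$profiles, paths$expression_profiles)
  readr::write_tsv(sim$de_table, paths$de_table)
  truth_wide <- sim$truth$enrichment |>
    tidyr::pivot_wider(names_from = c("mark", "condition"),
                       values_from = "rate", names_prefix = "rate_")
  readr::write_tsv(left_join(sim$truth$genes, truth_wide, by = "gene_id"),
                   paths$ground_truth)
  cfg <- sim$config
  cfg$enrichment_base <- apply(cfg$enrichment_base, 1, as.list,
                               simplify = FALSE)
  cfg$class_proportions <- as.list(cfg$class_proportions)
  yaml::write_yaml(cfg, paths$config)
  for (nm in names(sim$fragments)) {
    p <- file.path(frag_dir, paste0(nm, ".bed"))
    write_fragments(sim$fragments[[nm]], p)
    paths[[paste0("fragments_", nm)]] <- p
  }
  invisible(paths)
}
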