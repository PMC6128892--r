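# Independent oracles used to cross-check package computations.
# These deliberately use naive, brute-force formulations.

# Upper-tail hypergeometric probability as an explicit PMF sum over
# binomial coefficients (exact in double precision for N <= 30).
oracle_hyper_upper <- function(N, K, n, k) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# The same probability by literally enumerating every possible draw of
# size n from the universe (only feasible for tiny N).
oracle_hyper_enumerate <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Average ranks computed from first principles (no call to rank()).
oracle_avg_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman rho from the definitional formula on hand-computed ranks.
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Recursive permutation generator (independent of the package's iterative
# construction), returning a list of integer vectors.
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- oracle_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Exact two-sided permutation p-value for Spearman rho via enumeration.
oracle_spearman_exact_p <- function(x, y) {
  obs <- oracle_spearman_rho(x, y)
  rhos <- vapply(oracle_perms(length(y)),
                 function(p) oracle_spearman_rho(x, y[p]), numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Per-bin fragment coverage by scanning every (bin, fragment) pair.
oracle_coverage <- function(frags, chrom_len, bin_size) {
  n_bins <- ceiling(chrom_len / bin_size)
  vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_size
    hi <- min(b * bin_size, chrom_len)
    sum(frags$start < hi & frags$end > lo)
  }, numeric(1))
}

# Exhaustive application of the compartment-enrichment rule.
oracle_classify <- function(p1, p2, p3, unions = FALSE) {
  props <- c(X1 = p1, X2 = p2, Xins = p3)
  winners <- names(props)[props > 0.5]
  if (length(winners) == 1) return(winners)
  if (unions) {
    if (p1 + p2 > 0.5 && p1 >= 0.25 && p2 >= 0.25) return("X1X2")
    if (p2 + p3 > 0.5 && p2 >= 0.25 && p3 >= 0.25) return("X2Xins")
  }
  "none"
}

# Small simulated experiment shared by several tests.
tiny_sim_config <- function(seed = 7, ...) {
  simulation_config(
    seed = seed, n_genes = 40, chrom_len = 4e5, spike_chrom_len = 8e4,
    n_fragments = 2e4, n_de_up = 4, n_de_down = 4, ...
  )
}

# Constant-valued track helper on a toy genome.
constant_track <- function(value, chrom_len = 1e4, bin_size = 10,
                           state = "scaled", chrom = "chr1") {
  vals <- list(rep(value, ceiling(chrom_len / bin_size)))
  names(vals) <- chrom
  coverage_track(vals, bin_size, setNames(chrom_len, chrom), state = state)
}
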