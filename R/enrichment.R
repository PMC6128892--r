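#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts how many of `n` genes drawn without
#' replacement from a universe of `N` genes fall into a class of size `K` —
#' the exact enrichment p-value for an overlap of `k` genes.
#'
#' @param N Universe size.
#' @param K Class size (`K <= N`).
#' @param n Draw (gene-list) size (`n <= N`).
#' @param k Observed overlap (`0 <= k <= min(K, n)`).
#' @return The exact upper-tail probability, in (0, 1]. Vectorized over all
#'   arguments.
#' @examples
#' hypergeom_upper(10, 5, 4, 4) # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeom_upper <- function(N, K, n, k) {
  args <- vctrs_recycle(N = N, K = K, n = n, k = k)
  with(args, {
    bad <- K > N | n > N | k > pmin(K, n) | k < 0 | N < 0
    if (any(bad)) {
      cx_abort("Inconsistent hypergeometric arguments (need 0 <= k <= min(K, n) and K, n <= N).",
               "cx_validation_error")
    }
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, rep_len, length.out = len)
}

#' Class enrichment of up- and down-regulated gene lists
#'
#' For each direction (up, down) and each expression class, the
#' hypergeometric upper-tail probability of the observed overlap between the
#' DE list and the class, over the universe of all classified genes
#' (including class `none`). Significance is called at raw `p < alpha`
#' (default 0.01); a Benjamini-Hochberg column is emitted alongside.
#'
#' @param up,down Character vectors of gene ids (subsets of the universe).
#' @param class_labels Tibble `gene_id`, `class` — the classified universe.
#' @param alpha Raw-p significance threshold.
#' @return A tibble with one row per (direction, class): `direction`,
#'   `class`, `N`, `K`, `n`, `k`, `p_value`, `significant`, `p_adj`.
#' @export
enrich_de_lists <- function(up, down, class_labels, alpha = 0.01) {
  check_columns(class_labels, c("gene_id", "class"), "Class-label table")
  universe <- class_labels$gene_id
  offenders <- setdiff(c(up, down), universe)
  if (length(offenders) > 0L) {
    cx_abort(sprintf(
      "%d DE gene(s) missing from the classified universe: %s%s.",
      length(offenders), paste(head(offenders, 5), collapse = ", "),
      if (length(offenders) > 5) ", ..." else ""
    ), "cx_validation_error")
  }
  N <- length(universe)
  classes <- sort(unique(class_labels$class))
  lists <- list(up = up, down = down)
  out <- tidyr::expand_grid(direction = names(lists), class = classes) |>
    mutate(
      N = N,
      K = map_int(.data$class,
                  ~ sum(class_labels$class == .x)),
      n = lengths(lists)[.data$direction],
      k = map2_int(.data$direction, .data$class, function(d, cl) {
        length(intersect(lists[[d]],
                         class_labels$gene_id[class_labels$class == cl]))
      }),
      p_value = hypergeom_upper(.data$N, .data$K, .data$n, .data$k),
      significant = .data$p_value < alpha,
      p_adj = stats::p.adjust(.data$p_value, method = "BH")
    )
  out
}

#' Generic term enrichment ordered by mean log2 fold change
#'
#' Hypergeometric enrichment of a gene list against a user-supplied
#' gene-to-term map (e.g. GO annotations obtained elsewhere), reporting per
#' term the overlap, the exact upper-tail p-value and the mean log2 fold
#' change of the list genes annotated with the term; rows are ordered by
#' that mean (decreasing), with ties broken deterministically by term id.
#'
#' @param gene_list Character vector of gene ids (e.g. the up- or
#'   down-regulated list).
#' @param term_map Tibble `gene_id`, `term_id`; its distinct gene ids form
#'   the enrichment universe.
#' @param de_table Tibble `gene_id`, `log2fc` supplying the fold changes.
#' @return A tibble `term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `mean_log2fc`, sorted by `mean_log2fc` (descending, ties by term id).
#' @export
term_enrichment <- function(gene_list, term_map, de_table) {
  check_columns(term_map, c("gene_id", "term_id"), "Term map")
  check_columns(de_table, c("gene_id", "log2fc"), "DE table")
  if (nrow(term_map) == 0L) {
    return(tibble(term_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = double(),
                  mean_log2fc = double()))
  }
  term_map <- distinct(term_map, .data$gene_id, .data$term_id)
  universe <- unique(term_map$gene_id)
  N <- length(universe)
  in_list <- intersect(gene_list, universe)
  n <- length(in_list)
  fc <- setNames(de_table$log2fc, de_table$gene_id)
  out <- term_map |>
    group_by(.data$term_id) |>
    summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = length(intersect(.data$gene_id, in_list)),
      mean_log2fc = mean(fc[intersect(.data$gene_id, in_list)]),
      .groups = "drop"
    )
  empty <- out$K == 0L
  if (any(empty)) {
    rlang::warn(sprintf("%d term(s) with no universe genes skipped.",
                        sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  out |>
    mutate(n = n, N = N,
           p_value = hypergeom_upper(N, .data$K, n, .data$k)) |>
    arrange(desc(.data$mean_log2fc), .data$term_id) |>
    select("term_id", "k", "K", "n", "N", "p_value", "mean_log2fc")
}
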