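#' Per-gene signal change between conditions
#'
#' For every gene, the difference in mean normalized signal between
#' knockdown and control over either a strand-agnostic window around the TSS
#' (`region = "tss_window"`, default +/- 2 kb) or the gene body
#' (`region = "gene_body"`). Genes whose TSS window runs past a chromosome
#' end are skipped and reported.
#'
#' @param kd_track,ctrl_track [coverage_track()]s in the same normalization
#'   state and bin layout.
#' @param genes Gene tibble.
#' @param region `"tss_window"` or `"gene_body"`.
#' @param window Half-width in bp of the TSS window (default 2000).
#' @return A tibble `gene_id`, `region`, `delta` (knockdown minus control
#'   mean signal, in normalized signal units), with skipped gene ids in
#'   attribute `"skipped"`.
#' @export
gene_signal_change <- function(kd_track, ctrl_track, genes,
                               region = c("tss_window", "gene_body"),
                               window = 2000) {
  region <- match.arg(region)
  check_scalar_number(window, "window", min = 0, strict_min = TRUE)
  if (kd_track$state != ctrl_track$state) {
    cx_abort("Tracks must share a normalization state.",
             "cx_validation_error")
  }
  stopifnot_same_shape(kd_track, ctrl_track)
  bs <- kd_track$bin_size
  check_columns(genes, c("gene_id", "chrom", "start", "end", "tss"),
                "Gene table")
  n_bins <- setNames(
    map_int(names(kd_track$values), ~ length(kd_track$values[[.x]])),
    names(kd_track$values)
  )
  if (region == "tss_window") {
    first <- floor((genes$tss - window) / bs) + 1L
    last <- ceiling((genes$tss + window) / bs)
  } else {
    first <- floor(genes$start / bs) + 1L
    last <- ceiling(genes$end / bs)
  }
  keep <- first >= 1L & last <= n_bins[genes$chrom]
  skipped <- genes$gene_id[!keep]
  if (length(skipped) > 0L) {
    rlang::inform(sprintf("%d gene(s) skipped: %s region exceeds chromosome.",
                          length(skipped), region))
  }
  delta <- unname(map_dbl(unname(which(keep)), function(i) {
    idx <- first[i]:last[i]
    mean(kd_track$values[[genes$chrom[i]]][idx]) -
      mean(ctrl_track$values[[genes$chrom[i]]][idx])
  }))
  out <- tibble(gene_id = genes$gene_id[keep], region = region, delta = delta)
  attr(out, "skipped") <- skipped
  out
}

#' Spearman rank correlation with explicit tie and p-value policy
#'
#' Ranks both vectors with average ranks for ties and takes the Pearson
#' correlation of the ranks. The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom for
#' `n >= 10`, and exact enumeration over all `n!` permutations for `n < 10`
#' (so a perfect monotone relation on distinct values gives `p = 2 / n!`).
#' Under the approximation, `|rho| = 1` yields `p = 0` with a warning.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`; constant input has no
#'   defined rank correlation and raises an error.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` picks it for `n < 10`.
#' @return An object of class `spearman_cor`: list with `rho`, `p_value`,
#'   `n`, `method` (`"exact"` or `"t-approximation"`).
#' @examples
#' spearman_cor(1:4, c(10, 20, 15, 40))
#' @export
spearman_cor <- function(x, y, exact = NULL) {
  if (length(x) != length(y)) {
    cx_abort("`x` and `y` must have equal length.", "cx_validation_error")
  }
  n <- length(x)
  if (n < 3L) {
    cx_abort("Spearman correlation needs at least 3 observations.",
             "cx_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    cx_abort("Missing values are not allowed.", "cx_validation_error")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    cx_abort("Rank correlation is undefined for a constant vector.",
             "cx_constant_input")
  }
  rx <- rank(x)  # average ranks for ties
  ry <- rank(y)
  rho <- cor(rx, ry)
  exact <- exact %||% (n < 10L)
  if (exact) {
    p <- exact_spearman_p(rx, ry, rho)
    method <- "exact"
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      rlang::warn("|rho| = 1 under the t approximation: p-value reported as 0.")
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "spearman_cor")
}

# Two-sided exact permutation p-value: the proportion of permutations of y
# whose rank correlation is at least as extreme as the observed one.
exact_spearman_p <- function(rx, ry, rho) {
  n <- length(rx)
  perms <- permutation_matrix(n)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  rho_perm <- as.numeric(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) /
    denom
  mean(abs(rho_perm) >= abs(rho) - 1e-12)
}

# all permutations of 1..n as a (n!) x n integer matrix, built iteratively
permutation_matrix <- function(n) {
  out <- matrix(1L, nrow = 1, ncol = 1)
  for (k in 2:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      cbind(out[, seq_len(pos - 1), drop = FALSE], k,
            out[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    })
    out <- do.call(rbind, blocks)
  }
  out
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("<spearman_cor> rho = %.4f, p = %.3g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' @method tidy spearman_cor
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n, method = x$method)
}

#' @method glance spearman_cor
#' @export
glance.spearman_cor <- function(x, ...) tidy.spearman_cor(x, ...)

#' Correlate mark changes with expression changes per class
#'
#' Joins a differential-expression table, per-gene signal changes (possibly
#' for several marks and regions) and class labels, then computes the
#' Spearman correlation between signal change and expression log2 fold
#' change for every (class, mark, region) combination — optionally after the
#' fold-change filter that keeps only genes with `|log2fc| >= 1`.
#' Significance uses the `p < corr_alpha` rule (default 0.001); a
#' Benjamini-Hochberg adjusted column is emitted alongside for transparency.
#'
#' @param de_table Tibble `gene_id`, `log2fc`, `p_value`.
#' @param signal_changes Tibble `gene_id`, `mark`, `region`, `delta`
#'   ([gene_signal_change()] output with a `mark` column added, or several
#'   bound together).
#' @param class_labels Tibble `gene_id`, `class`.
#' @param fc_filter `"none"` or `"abs_log2fc_ge_1"`.
#' @param corr_alpha Significance threshold on the per-test p-value.
#' @return A tibble of class `class_correlation`: one row per
#'   (class, mark, region) with `filter`, `n`, `rho`, `p_value`,
#'   `significant`, `p_adj` and a `reason` column (`NA` unless the joined
#'   set was too small, in which case `rho` is `NA` with reason
#'   `"n_lt_3"`). The number of genes excluded by the join is attribute
#'   `"n_unjoined"`.
#' @export
correlate_by_class <- function(de_table, signal_changes, class_labels,
                               fc_filter = c("none", "abs_log2fc_ge_1"),
                               corr_alpha = 0.001) {
  fc_filter <- match.arg(fc_filter)
  check_columns(de_table, c("gene_id", "log2fc"), "DE table")
  check_columns(signal_changes, c("gene_id", "mark", "region", "delta"),
                "Signal-change table")
  check_columns(class_labels, c("gene_id", "class"), "Class-label table")
  joined <- signal_changes |>
    inner_join(select(de_table, "gene_id", "log2fc"), by = "gene_id") |>
    inner_join(class_labels, by = "gene_id")
  n_unjoined <- length(setdiff(signal_changes$gene_id, joined$gene_id))
  if (n_unjoined > 0L) {
    rlang::inform(sprintf(
      "%d gene(s) excluded: missing from the DE or class table.", n_unjoined
    ))
  }
  if (fc_filter == "abs_log2fc_ge_1") {
    joined <- filter(joined, abs(.data$log2fc) >= 1)
  }
  out <- joined |>
    group_by(.data$class, .data$mark, .data$region) |>
    summarise(result = list(safe_spearman(.data$delta, .data$log2fc)),
              .groups = "drop") |>
    tidyr::unnest_wider("result") |>
    mutate(filter = fc_filter,
           significant = !is.na(.data$p_value) &
             .data$p_value < corr_alpha,
           p_adj = stats::p.adjust(.data$p_value, method = "BH")) |>
    select("class", "mark", "region", "filter", "n", "rho", "p_value",
           "significant", "p_adj", "reason")
  attr(out, "n_unjoined") <- n_unjoined
  class(out) <- c("class_correlation", class(out))
  out
}

safe_spearman <- function(delta, log2fc) {
  if (length(delta) < 3L) {
    return(list(n = length(delta), rho = NA_real_, p_value = NA_real_,
                reason = "n_lt_3"))
  }
  res <- spearman_cor(delta, log2fc)
  list(n = res$n, rho = res$rho, p_value = res$p_value,
       reason = NA_character_)
}

#' Plot per-class correlation results
#'
#' Bars of the Spearman rho per class, faceted by mark and region; bars not
#' significant at the configured threshold are faded, echoing the
#' significance shading of correlation panels.
#'
#' @param object A [correlate_by_class()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot class_correlation
#' @export
autoplot.class_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$class, y = .data$rho, fill = .data$class,
    alpha = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::facet_grid(ggplot2::vars(.data$region),
                        ggplot2::vars(.data$mark, .data$filter)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = "Expression class", y = "Spearman rho",
                  alpha = "Significant")
}
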