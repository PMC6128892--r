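#' Select differentially expressed genes by fold change and p-value
#'
#' Applies the conventional two-sided threshold rule to a precomputed
#' differential-expression table: a gene is up-regulated when
#' `log2fc >= log2(fc_threshold)` and `p < alpha`, down-regulated when
#' `log2fc <= -log2(fc_threshold)` and `p < alpha`. The fold-change bound is
#' inclusive and the p-value bound strict, matching the usual
#' "fold change >= 1.5, p < 0.05" phrasing.
#'
#' @param de_table Tibble with columns `gene_id`, `log2fc`, `p_value`
#'   (names configurable). Additional columns (e.g. q-values) are passed
#'   through untouched.
#' @param fc_threshold Linear fold-change threshold (> 1, default 1.5).
#' @param alpha P-value threshold (default 0.05).
#' @param cols Optional named character vector remapping the three required
#'   column names, e.g. `c(gene_id = "target_id", log2fc = "b")`.
#' @return A list of class `de_selection` with `up` and `down` (character
#'   vectors of gene ids) and `table` (the input with a derived `status`
#'   column: `"up"`, `"down"` or `"unchanged"`).
#' @export
select_de <- function(de_table, fc_threshold = 1.5, alpha = 0.05,
                      cols = NULL) {
  check_scalar_number(fc_threshold, "fc_threshold", min = 1,
                      strict_min = TRUE)
  check_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE,
                      strict_max = TRUE)
  if (!is.null(cols)) {
    for (std in names(cols)) {
      names(de_table)[names(de_table) == cols[[std]]] <- std
    }
  }
  check_columns(de_table, c("gene_id", "log2fc", "p_value"), "DE table")
  b <- log2(fc_threshold)
  table <- de_table |>
    mutate(status = case_when(
      .data$log2fc >= b & .data$p_value < alpha ~ "up",
      .data$log2fc <= -b & .data$p_value < alpha ~ "down",
      TRUE ~ "unchanged"
    ))
  structure(
    list(up = table$gene_id[table$status == "up"],
         down = table$gene_id[table$status == "down"],
         table = table,
         fc_threshold = fc_threshold, alpha = alpha),
    class = "de_selection"
  )
}

#' @export
print.de_selection <- function(x, ...) {
  cat(sprintf(
    "<de_selection> %d up, %d down of %d genes (|FC| >= %.3g, p < %.3g)\n",
    length(x$up), length(x$down), nrow(x$table), x$fc_threshold, x$alpha
  ))
  invisible(x)
}

#' @method tidy de_selection
#' @export
tidy.de_selection <- function(x, ...) x$table

#' @method glance de_selection
#' @export
glance.de_selection <- function(x, ...) {
  tibble(n_genes = nrow(x$table), n_up = length(x$up),
         n_down = length(x$down), fc_threshold = x$fc_threshold,
         alpha = x$alpha)
}

#' Convert signed linear fold changes to log2 fold changes
#'
#' Maps the signed linear convention (where -1.5 means a 1.5-fold decrease)
#' onto the log2 scale sign-preservingly: `sign(x) * log2(|x|)`, so
#' `+1.5 -> +0.585`, `-2 -> -1`, `+1 -> 0`.
#'
#' @param fold_change Signed linear fold change(s), expected magnitude
#'   >= 1; zero is undefined.
#' @return log2 fold change(s).
#' @examples
#' log2_transform_fc(c(1.5, -2, 1)) # 0.585, -1, 0
#' @export
log2_transform_fc <- function(fold_change) {
  if (any(fold_change == 0)) {
    cx_abort("Fold change of 0 has no log2 transform.",
             "cx_validation_error")
  }
  sign(fold_change) * log2(abs(fold_change))
}
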