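#' Classify one expression profile into a compartment-enrichment class
#'
#' A gene is enriched in a FACS compartment when strictly more than 50% of
#' its expression is observed in that compartment; profiles with no
#' compartment above 50% are `none`. With `unions = TRUE`, profiles failing
#' the single-compartment rule may fall into an adjacent union class
#' (`X1X2` or `X2Xins`) when the two compartments jointly exceed 50% and
#' each contributes at least 25%.
#'
#' @param prop_X1,prop_X2,prop_Xins Proportions of expression in the X1
#'   (G2/M stem cells), X2 (G1 stem cells and progeny) and Xins
#'   (differentiated cells) compartments; must sum to 1 within 1e-6.
#' @param unions Allow adjacent union classes?
#' @param cutoff Enrichment cutoff (default 0.5; the comparison is strict,
#'   so exactly 50% is not enriched).
#' @return A single class label.
#' @examples
#' classify_profile(0.6, 0.3, 0.1)   # "X1"
#' classify_profile(0.5, 0.25, 0.25) # "none": the rule is strict
#' @export
classify_profile <- function(prop_X1, prop_X2, prop_Xins, unions = FALSE,
                             cutoff = 0.5) {
  props <- c(X1 = prop_X1, X2 = prop_X2, Xins = prop_Xins)
  if (any(props < 0) || any(props > 1) || abs(sum(props) - 1) > 1e-6) {
    cx_abort("Expression proportions must lie in [0,1] and sum to 1.",
             "cx_validation_error")
  }
  single <- names(props)[props > cutoff]
  if (length(single) == 1L) return(single)
  if (unions) {
    for (pair in list(c("X1", "X2"), c("X2", "Xins"))) {
      if (sum(props[pair]) > cutoff && all(props[pair] >= cutoff / 2)) {
        return(paste0(pair, collapse = ""))
      }
    }
  }
  "none"
}

#' Classify a table of expression profiles
#'
#' Vectorized application of the >50% rule over a profile table, plus a
#' class-size summary.
#'
#' @param profiles Tibble with columns `gene_id`, `prop_X1`, `prop_X2`,
#'   `prop_Xins`; `gene_id` must be unique.
#' @inheritParams classify_profile
#' @return A tibble `gene_id`, `class`, carrying the class-size summary as
#'   attribute `"class_sizes"` (a named integer vector).
#' @export
classify_expression <- function(profiles, unions = FALSE, cutoff = 0.5) {
  check_columns(profiles, c("gene_id", "prop_X1", "prop_X2", "prop_Xins"),
                "Expression-profile table")
  if (anyDuplicated(profiles$gene_id)) {
    dup <- profiles$gene_id[duplicated(profiles$gene_id)][1]
    cx_abort(sprintf("Duplicate gene_id '%s' in profile table.", dup),
             "cx_validation_error")
  }
  labels <- purrr::pmap_chr(
    profiles[c("prop_X1", "prop_X2", "prop_Xins")],
    classify_profile, unions = unions, cutoff = cutoff
  )
  out <- tibble(gene_id = profiles$gene_id, class = labels)
  sizes <- table(factor(labels, levels = unique(c("X1", "X2", "Xins", "none",
                                                  labels))))
  attr(out, "class_sizes") <- setNames(as.integer(sizes), names(sizes))
  out
}
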