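#' Extract TSS-centered signal windows for every gene
#'
#' Builds the genes x bins matrix behind a metagene plot: for each gene the
#' track values in `[tss - flank, tss + flank)` (on the bin grid through the
#' TSS bin), oriented so that column 1 is always the 5' (upstream) end in
#' gene orientation — minus-strand rows are reversed relative to genome
#' order. Genes whose window runs past a chromosome end are dropped and
#' recorded.
#'
#' @param track A scaled- or subtracted-state [coverage_track()].
#' @param genes Gene tibble (needs `gene_id`, `chrom`, `strand`, `tss`).
#' @param flank Half-window in bp (default 2000, i.e. 2 kb upstream and
#'   downstream); must be a multiple of the track bin size.
#' @return An object of class `profile_matrix`: a numeric matrix with
#'   gene-id rownames and attributes `positions` (bp offset of each column's
#'   bin start relative to the TSS bin start, upstream negative), `bin_size`,
#'   `flank` and `dropped` (ids of genes without a full window).
#' @export
tss_profile_matrix <- function(track, genes, flank = 2000) {
  if (!track$state %in% c("scaled", "subtracted")) {
    cx_abort("Metagene extraction expects a scaled or subtracted track.",
             "cx_validation_error")
  }
  bs <- track$bin_size
  if (flank %% bs != 0) {
    cx_abort("`flank` must be a multiple of the track bin size.",
             "cx_validation_error")
  }
  check_columns(genes, c("gene_id", "chrom", "strand", "tss"), "Gene table")
  n_half <- flank / bs
  n_cols <- 2L * n_half
  tss_bin <- floor(genes$tss / bs) + 1L  # 1-based bin holding the TSS
  n_bins <- map_int(genes$chrom, function(chrom) {
    if (!chrom %in% names(track$values)) {
      cx_abort(sprintf("Track has no chromosome '%s'.", chrom),
               "cx_validation_error")
    }
    length(track$values[[chrom]])
  })
  keep <- tss_bin - n_half >= 1L & tss_bin + n_half - 1L <= n_bins
  dropped <- genes$gene_id[!keep]
  if (length(dropped) > 0L) {
    rlang::inform(sprintf(
      "%d gene(s) dropped: TSS window exceeds a chromosome end.",
      length(dropped)
    ))
  }
  kept <- genes[keep, , drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(kept), ncol = n_cols,
                dimnames = list(kept$gene_id, NULL))
  for (i in seq_len(nrow(kept))) {
    b <- tss_bin[keep][i]
    row <- track$values[[kept$chrom[i]]][(b - n_half):(b + n_half - 1L)]
    if (kept$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  structure(mat, class = c("profile_matrix", "matrix", "array"),
            positions = seq(-flank, flank - bs, by = bs),
            bin_size = bs, flank = flank, dropped = dropped)
}

#' Tidy a profile matrix into a long tibble
#'
#' @param x A [tss_profile_matrix()] result.
#' @param ... Unused.
#' @return A tibble `gene_id`, `position`, `value`.
#' @method tidy profile_matrix
#' @export
tidy.profile_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x), each = ncol(x)),
    position = rep(attr(x, "positions"), times = nrow(x)),
    value = as.numeric(t(unclass(x)))
  )
}

#' Average TSS windows into per-class metagene profiles
#'
#' For each expression class and each bin, the arithmetic mean and the
#' population standard deviation (the dispersion band of a metagene plot)
#' over the genes of that class.
#'
#' @param profile_mat A [tss_profile_matrix()] result.
#' @param class_labels Tibble `gene_id`, `class` covering every matrix row.
#' @return A tibble of class `metagene_profile` with columns `class`,
#'   `position`, `mean`, `sd`, `n`.
#' @export
metagene_aggregate <- function(profile_mat, class_labels) {
  check_columns(class_labels, c("gene_id", "class"), "Class-label table")
  ids <- rownames(profile_mat)
  cls <- class_labels$class[match(ids, class_labels$gene_id)]
  if (anyNA(cls)) {
    cx_abort(sprintf("No class label for gene(s): %s.",
                     paste(head(ids[is.na(cls)], 3), collapse = ", ")),
             "cx_validation_error")
  }
  empty <- setdiff(unique(class_labels$class), unique(cls))
  if (length(empty) > 0L) {
    rlang::warn(sprintf("Class(es) with no profiled genes omitted: %s.",
                        paste(empty, collapse = ", ")))
  }
  positions <- attr(profile_mat, "positions")
  out <- purrr::map(sort(unique(cls)), function(cl) {
    rows <- unclass(profile_mat)[cls == cl, , drop = FALSE]
    tibble(
      class = cl, position = positions,
      mean = colMeans(rows),
      sd = sqrt(colMeans(rows^2) - colMeans(rows)^2),
      n = nrow(rows)
    )
  }) |>
    bind_rows()
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Between-condition log2-ratio metagene profile
#'
#' Per class and bin, `log2((knockdown + pseudocount) /
#' (control + pseudocount))`: values above zero mean a gain of signal after
#' knockdown. Intended for scaled (pre-subtraction) profiles, which are
#' non-negative; the pseudocount guards empty bins.
#'
#' @param knockdown,control [metagene_aggregate()] results with identical
#'   classes and bins.
#' @param pseudocount Positive stabilizer added to both means (default 1).
#' @return A tibble `class`, `position`, `log2_ratio`.
#' @export
log2_ratio_profile <- function(knockdown, control, pseudocount = 1) {
  check_scalar_number(pseudocount, "pseudocount", min = 0, strict_min = TRUE)
  if (!identical(dim(knockdown)[1], dim(control)[1]) ||
      !identical(knockdown$class, control$class) ||
      !identical(knockdown$position, control$position)) {
    cx_abort("Profiles differ in classes or bins.", "cx_validation_error")
  }
  tibble(
    class = knockdown$class, position = knockdown$position,
    log2_ratio = log2((knockdown$mean + pseudocount) /
                        (control$mean + pseudocount))
  )
}

#' Plot a metagene profile
#'
#' Mean line per class with a +/- 1 SD ribbon, centered on the TSS.
#'
#' @param object A [metagene_aggregate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$position, y = .data$mean,
    ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
    colour = .data$class, fill = .data$class
  )) +
    ggplot2::geom_ribbon(alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Position relative to TSS (bp)",
                  y = "Normalized signal", colour = "Class", fill = "Class")
}
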