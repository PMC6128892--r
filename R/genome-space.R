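#' Define a combined target + spike-in genome space
#'
#' A genome space records the chromosome sizes of the combined reference the
#' fragments were aligned to and the naming convention that separates the
#' exogenous spike-in chromosomes (e.g. *Drosophila* S2 chromatin added before
#' library preparation) from the target-organism chromosomes. Membership is
#' decided purely by chromosome name: any chromosome whose name starts with
#' `spike_prefix` belongs to the spike-in genome.
#'
#' @param chrom_sizes Named numeric vector or two-column data frame
#'   (`chrom`, `length`) of chromosome lengths in bp.
#' @param spike_prefix Prefix marking spike-in chromosome names
#'   (default `"spike_"`).
#'
#' @return An object of class `genome_space` with elements `chrom_sizes`
#'   (named numeric) and `spike_prefix`.
#' @examples
#' gs <- genome_space(c(chr1 = 1e6, spike_chr1 = 2e5))
#' spike_chroms(gs)
#' @export
genome_space <- function(chrom_sizes, spike_prefix = "spike_") {
  if (is.data.frame(chrom_sizes)) {
    check_columns(chrom_sizes, c("chrom", "length"), "chrom_sizes table")
    chrom_sizes <- setNames(as.numeric(chrom_sizes$length),
                            as.character(chrom_sizes$chrom))
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    cx_abort("`chrom_sizes` must be named by chromosome.",
             "cx_validation_error")
  }
  if (anyDuplicated(names(chrom_sizes))) {
    cx_abort("Chromosome names must be unique.", "cx_validation_error")
  }
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    cx_abort("All chromosome lengths must be positive.",
             "cx_validation_error")
  }
  if (!is.character(spike_prefix) || length(spike_prefix) != 1L ||
      !nzchar(spike_prefix)) {
    cx_abort("`spike_prefix` must be a non-empty string.",
             "cx_validation_error")
  }
  structure(
    list(chrom_sizes = chrom_sizes, spike_prefix = spike_prefix),
    class = "genome_space"
  )
}

#' Read a two-column chromosome-size table
#'
#' @param path Tab-delimited file with columns chromosome name and length
#'   (no header).
#' @inheritParams genome_space
#' @return A [genome_space()] object.
#' @export
read_chrom_sizes <- function(path, spike_prefix = "spike_") {
  if (!file.exists(path)) {
    cx_abort(sprintf("Chromosome-size file not found: %s", path),
             "cx_io_error")
  }
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "cd", progress = FALSE)
  genome_space(tab, spike_prefix = spike_prefix)
}

#' @export
print.genome_space <- function(x, ...) {
  n_spike <- length(spike_chroms(x))
  cat(sprintf(
    "<genome_space> %d chromosome(s): %d target, %d spike-in (prefix '%s')\n",
    length(x$chrom_sizes), length(x$chrom_sizes) - n_spike, n_spike,
    x$spike_prefix
  ))
  invisible(x)
}

is_spike_chrom <- function(space, chrom) {
  startsWith(chrom, space$spike_prefix)
}

#' Chromosome names of the spike-in / target genome
#' @param space A [genome_space()].
#' @return Character vector of chromosome names.
#' @export
spike_chroms <- function(space) {
  names(space$chrom_sizes)[is_spike_chrom(space, names(space$chrom_sizes))]
}

#' @rdname spike_chroms
#' @export
target_chroms <- function(space) {
  names(space$chrom_sizes)[!is_spike_chrom(space, names(space$chrom_sizes))]
}

check_chroms_known <- function(chroms, space, what) {
  unknown <- setdiff(unique(chroms), names(space$chrom_sizes))
  if (length(unknown) > 0L) {
    cx_abort(sprintf("%s on chromosome(s) absent from the genome space: %s.",
                     what, paste(unknown, collapse = ", ")),
             "cx_validation_error")
  }
  invisible(chroms)
}
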