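#' Read aligned fragments from a BED file
#'
#' Fragments are the deduplicatable unit of ChIP-seq signal here: one interval
#' per (properly paired) sequenced DNA fragment, in 0-based half-open
#' coordinates on the combined target + spike-in reference. A 3-column BED is
#' accepted; strand is taken from column 6 when present, otherwise `"+"`.
#'
#' @param path BED file (>= 3 columns, tab-delimited, no header).
#' @param space A [genome_space()] used to validate chromosome names and
#'   interval bounds.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_fragments <- function(path, space) {
  if (!file.exists(path)) {
    cx_abort(sprintf("Fragment file not found: %s", path), "cx_io_error")
  }
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0L) {
    rlang::warn(sprintf("Fragment file %s is empty.", path))
    return(tibble(chrom = character(), start = double(),
                  end = double(), strand = character()))
  }
  if (ncol(raw) < 3L) {
    cx_abort("Fragment BED needs at least 3 columns.", "cx_parse_error")
  }
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    cx_abort(sprintf("Malformed BED coordinates at line %d of %s.",
                     bad[1], path), "cx_parse_error")
  }
  frags <- tibble(
    chrom = raw[[1]], start = start, end = end,
    strand = if (ncol(raw) >= 6L) normalise_strand(raw[[6]], path) else
      rep("+", nrow(raw))
  )
  validate_fragments(frags, space, path)
}

validate_fragments <- function(frags, space, path = "<in-memory>") {
  bad <- which(!(frags$start < frags$end))
  if (length(bad) > 0L) {
    cx_abort(sprintf("Fragment at line %d of %s has end <= start.",
                     bad[1], path), "cx_validation_error")
  }
  check_chroms_known(frags$chrom, space, "Fragment(s)")
  beyond <- which(frags$end > space$chrom_sizes[frags$chrom] |
                    frags$start < 0)
  if (length(beyond) > 0L) {
    cx_abort(sprintf("Fragment at line %d of %s extends beyond chromosome %s.",
                     beyond[1], path, frags$chrom[beyond[1]]),
             "cx_validation_error")
  }
  frags
}

#' Write fragments as BED6
#'
#' @param frags Fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  check_columns(frags, c("chrom", "start", "end", "strand"), "Fragment table")
  readr::write_tsv(
    tibble(frags$chrom, format_bp(frags$start), format_bp(frags$end),
           ".", 0L, frags$strand),
    path, col_names = FALSE
  )
  invisible(path)
}
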