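#' Write a coverage track as bedGraph
#'
#' Adjacent bins with equal values are merged into single intervals
#' (run-length encoding) and values are written with fixed 6-decimal
#' precision, so re-reading the file reproduces the track values up to that
#' precision (exactly, for integer-valued raw tracks).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bp <- c(0, head(ends_bin, -1)) * track$bin_size
    ends_bp <- pmin(ends_bin * track$bin_size, track$chrom_sizes[[chrom]])
    writeLines(sprintf("%s\t%s\t%s\t%.6f", chrom, format_bp(starts_bp),
                       format_bp(ends_bp), r$values), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Intervals are expanded onto the bin grid; positions not covered by any
#' interval get value 0. Intervals are assumed to be bin-aligned, as produced
#' by [write_bedgraph()].
#'
#' @param path bedGraph file.
#' @param space A [genome_space()] providing chromosome lengths.
#' @param bin_size Bin width in bp (must match the written track).
#' @param chroms Chromosomes to load (default: all intervals' chromosomes).
#' @inheritParams coverage_track
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, space, bin_size = 10, chroms = NULL,
                          sample_id = NA_character_, mark = NA_character_,
                          condition = NA_character_, state = "raw") {
  if (!file.exists(path)) {
    cx_abort(sprintf("bedGraph file not found: %s", path), "cx_io_error")
  }
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  check_chroms_known(tab$chrom, space, "bedGraph interval(s)")
  chroms <- chroms %||% unique(tab$chrom)
  values <- lapply(chroms, function(chrom) {
    len <- space$chrom_sizes[[chrom]]
    v <- numeric(ceiling(len / bin_size))
    sub <- tab[tab$chrom == chrom, , drop = FALSE]
    if (nrow(sub) > 0L) {
      first_bin <- floor(sub$start / bin_size) + 1
      last_bin <- ceiling(sub$end / bin_size)
      for (i in seq_len(nrow(sub))) {
        v[first_bin[i]:last_bin[i]] <- sub$value[i]
      }
    }
    v
  })
  names(values) <- chroms
  coverage_track(values, bin_size, space$chrom_sizes[chroms],
                 sample_id = sample_id, mark = mark, condition = condition,
                 state = state)
}
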