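#' Binned coverage tracks
#'
#' A `coverage_track` holds per-chromosome vectors of binned signal at a fixed
#' bin size, together with sample metadata and a normalization `state` that
#' can only move forward: `"raw"` (fragment counts per bin), `"scaled"`
#' (multiplied by a scale factor) and `"subtracted"` (scaled ChIP minus
#' scaled input). Each chromosome vector has `ceiling(chrom_len / bin_size)`
#' bins; bin `i` covers `[(i-1)*bin_size, i*bin_size)` clipped to the
#' chromosome end.
#'
#' @param values Named list of numeric bin vectors, one per chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of the lengths of the chromosomes
#'   present in `values`.
#' @param sample_id,mark,condition Free-text metadata carried through the
#'   pipeline and into output files.
#' @param state Normalization state.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_size, chrom_sizes,
                           sample_id = NA_character_, mark = NA_character_,
                           condition = NA_character_, state = "raw") {
  if (!is.list(values) || is.null(names(values))) {
    cx_abort("`values` must be a named list of numeric vectors.",
             "cx_validation_error")
  }
  state <- match.arg(state, c("raw", "scaled", "subtracted"))
  check_scalar_number(bin_size, "bin_size", min = 1)
  for (chrom in names(values)) {
    expect_len <- ceiling(chrom_sizes[[chrom]] / bin_size)
    if (length(values[[chrom]]) != expect_len) {
      cx_abort(sprintf(
        "Track vector for %s has %d bins; expected %d for length %s at bin %s.",
        chrom, length(values[[chrom]]), expect_len,
        format_bp(chrom_sizes[[chrom]]), format_bp(bin_size)
      ), "cx_validation_error")
    }
  }
  structure(
    list(values = values, bin_size = bin_size,
         chrom_sizes = chrom_sizes[names(values)],
         sample_id = sample_id, mark = mark, condition = condition,
         state = state),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s | mark=%s condition=%s | bin=%s bp | state=%s | %d chromosome(s)\n",
    x$sample_id, x$mark, x$condition, format_bp(x$bin_size), x$state,
    length(x$values)
  ))
  invisible(x)
}

#' Tidy a coverage track into a bin-level tibble
#'
#' @param x A [coverage_track()].
#' @param ... Unused.
#' @return A tibble with `chrom`, `start`, `end`, `value` (one row per bin).
#' @method tidy coverage_track
#' @export
tidy.coverage_track <- function(x, ...) {
  purrr::imap(x$values, function(v, chrom_name) {
    start <- (seq_along(v) - 1) * x$bin_size
    tibble(chrom = chrom_name, start = start,
           end = pmin(start + x$bin_size, x$chrom_sizes[[chrom_name]]),
           value = as.numeric(v))
  }) |>
    bind_rows()
}

#' Genome-wide mean signal of a track
#'
#' Bin values are averaged weighting every bin equally; used for global
#' between-condition signal ratios.
#'
#' @param track A [coverage_track()].
#' @param chroms Optional subset of chromosomes (default: all in the track).
#' @return A single number.
#' @export
track_mean <- function(track, chroms = NULL) {
  chroms <- chroms %||% names(track$values)
  mean(unlist(track$values[chroms], use.names = FALSE))
}

stopifnot_same_shape <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(sort(names(a$values)), sort(names(b$values))) ||
      !all(map_int(names(a$values), ~ length(a$values[[.x]])) ==
             map_int(names(a$values), ~ length(b$values[[.x]])))) {
    cx_abort("Tracks differ in bin size or chromosome layout.",
             "cx_validation_error")
  }
  invisible(NULL)
}
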