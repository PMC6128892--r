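#' Partition fragments into target and spike-in genomes
#'
#' Fragments aligned to the combined reference are split by chromosome
#' namespace: a fragment belongs to the spike-in genome iff its chromosome
#' name carries the genome space's spike prefix. This is the dual-genome
#' separation step that makes reference-normalized (ChIP-Rx) scaling
#' possible.
#'
#' @param frags Fragment tibble (`chrom`, `start`, `end`, `strand`).
#' @param space A [genome_space()].
#' @return A list of class `partition_result` with elements `target`,
#'   `spike` (fragment tibbles) and `counts` (named integer vector
#'   `n_target`, `n_spike`).
#' @export
partition_fragments <- function(frags, space) {
  check_columns(frags, c("chrom", "start", "end"), "Fragment table")
  check_chroms_known(frags$chrom, space, "Fragment(s)")
  spike <- is_spike_chrom(space, frags$chrom)
  res <- list(
    target = frags[!spike, , drop = FALSE],
    spike = frags[spike, , drop = FALSE],
    counts = c(n_target = sum(!spike), n_spike = sum(spike))
  )
  class(res) <- "partition_result"
  res
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %d target + %d spike-in fragments\n",
              x$counts[["n_target"]], x$counts[["n_spike"]]))
  invisible(x)
}

#' Remove duplicate fragments
#'
#' Keeps exactly one representative (the first occurrence) per identical
#' `(chrom, start, end, strand)` tuple — the fragment-level analogue of
#' PCR-duplicate removal after mapping.
#'
#' @param frags Fragment tibble.
#' @return The deduplicated fragment tibble, in first-occurrence order.
#' @export
deduplicate_fragments <- function(frags) {
  check_columns(frags, c("chrom", "start", "end", "strand"), "Fragment table")
  distinct(frags, .data$chrom, .data$start, .data$end, .data$strand,
           .keep_all = TRUE)
}

#' Spike-in (reference-adjusted) scale factor
#'
#' The per-sample normalization constant of reference-normalized ChIP-seq:
#' signal is expressed per `reference_count` spike-in fragments, i.e.
#' `alpha = reference_count / spike_count`. Because the same amount of
#' exogenous chromatin was added to every sample, dividing by the recovered
#' spike-in yield places all samples on a common absolute scale and preserves
#' genuine genome-wide shifts that library-size normalization would erase.
#'
#' @param spike_count Number of (deduplicated) spike-in fragments; must be
#'   positive — a missing spike-in leaves the normalization undefined.
#' @param reference_count Presentation constant (default 1e6: "signal per
#'   million spike-in fragments"); only between-sample ratios matter.
#' @return An object of class `scale_factor` with fields `alpha`, `count`,
#'   `reference_count`, `method`.
#' @export
spike_scale_factor <- function(spike_count, reference_count = 1e6) {
  check_scalar_number(spike_count, "spike_count", min = 0, strict_min = TRUE)
  check_scalar_number(reference_count, "reference_count", min = 0,
                      strict_min = TRUE)
  new_scale_factor(reference_count / spike_count, spike_count,
                   reference_count, "spike")
}

#' Library-size (total-count) scale factor
#'
#' The conventional normalization a non-spike-in experiment would use:
#' signal per `reference_count` target-genome fragments. Provided as the
#' comparison arm that, by construction, cannot recover genuine global
#' shifts in signal.
#'
#' @param fragment_count Number of (deduplicated) target-genome fragments.
#' @inheritParams spike_scale_factor
#' @return A `scale_factor` object with `method = "library"`.
#' @export
library_size_factor <- function(fragment_count, reference_count = 1e6) {
  check_scalar_number(fragment_count, "fragment_count", min = 0,
                      strict_min = TRUE)
  new_scale_factor(reference_count / fragment_count, fragment_count,
                   reference_count, "library")
}

new_scale_factor <- function(alpha, count, reference_count, method) {
  structure(list(alpha = alpha, count = count,
                 reference_count = reference_count, method = method),
            class = "scale_factor")
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor> alpha = %.6g (%s; %s fragments per %s)\n",
              x$alpha, x$method, format_bp(x$count),
              format_bp(x$reference_count)))
  invisible(x)
}

#' Binned fragment coverage
#'
#' Counts, for every genomic bin, the fragments overlapping it by at least
#' 1 bp. A fragment spanning k bins contributes to all k, so the bin sum is
#' at least the fragment count.
#'
#' @param frags Fragment tibble, already partitioned to a single genome.
#' @param space A [genome_space()].
#' @param bin_size Bin width in bp (default 10).
#' @param chroms Chromosomes to tile (default: target chromosomes if all
#'   fragments are on the target genome, otherwise the fragments'
#'   chromosomes plus any requested).
#' @inheritParams coverage_track
#' @return A raw-state [coverage_track()].
#' @export
fragment_coverage <- function(frags, space, bin_size = 10, chroms = NULL,
                              sample_id = NA_character_,
                              mark = NA_character_,
                              condition = NA_character_) {
  check_columns(frags, c("chrom", "start", "end"), "Fragment table")
  check_chroms_known(frags$chrom, space, "Fragment(s)")
  if (is.null(chroms)) {
    on_spike <- is_spike_chrom(space, unique(frags$chrom))
    chroms <- if (any(on_spike)) unique(frags$chrom) else target_chroms(space)
  }
  values <- lapply(chroms, function(chrom) {
    len <- space$chrom_sizes[[chrom]]
    n_bins <- ceiling(len / bin_size)
    sub <- frags[frags$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L) return(numeric(n_bins))
    # difference-array accumulation over the bin range each fragment overlaps
    first_bin <- pmax(floor(sub$start / bin_size) + 1, 1)
    last_bin <- pmin(ceiling(sub$end / bin_size), n_bins)
    add <- tabulate(first_bin, nbins = n_bins + 1L)
    rem <- tabulate(last_bin + 1L, nbins = n_bins + 1L)
    head(cumsum(add - rem), n_bins)
  })
  names(values) <- chroms
  coverage_track(values, bin_size, space$chrom_sizes[chroms],
                 sample_id = sample_id, mark = mark, condition = condition,
                 state = "raw")
}

#' Apply a scale factor to a raw track
#'
#' @param track A raw-state [coverage_track()].
#' @param sf A [spike_scale_factor()] or [library_size_factor()].
#' @return A scaled-state track.
#' @export
scale_track <- function(track, sf) {
  if (track$state != "raw") {
    cx_abort("Only raw tracks can be scaled.", "cx_validation_error")
  }
  track$values <- lapply(track$values, function(v) v * sf$alpha)
  track$state <- "scaled"
  track
}

#' Scale-and-subtract input from ChIP coverage
#'
#' Produces the normalized signal the downstream analyses consume:
#' `chip_sf$alpha * chip - input_sf$alpha * input` per bin. Negative values
#' are retained by default; `clip_negative = TRUE` truncates them at 0 for
#' display.
#'
#' @param chip,input Raw-state [coverage_track()]s on the same bin grid.
#' @param chip_sf,input_sf Scale factors for the two samples.
#' @param clip_negative Truncate negative post-subtraction values at 0?
#' @return A subtracted-state [coverage_track()].
#' @export
normalize_subtract <- function(chip, input, chip_sf, input_sf,
                               clip_negative = FALSE) {
  if (chip$state != "raw" || input$state != "raw") {
    cx_abort("normalize_subtract() expects raw tracks.",
             "cx_validation_error")
  }
  stopifnot_same_shape(chip, input)
  out <- chip
  out$values <- lapply(names(chip$values), function(chrom) {
    v <- chip_sf$alpha * chip$values[[chrom]] -
      input_sf$alpha * input$values[[chrom]]
    if (clip_negative) v[v < 0] <- 0
    v
  })
  names(out$values) <- names(chip$values)
  out$state <- "subtracted"
  out
}

#' Average several tracks bin-wise
#'
#' Used to combine replicate tracks after normalization.
#'
#' @param tracks List of [coverage_track()]s in the same state and layout.
#' @return A track of the same state with bin-wise mean values.
#' @export
average_tracks <- function(tracks) {
  if (length(tracks) == 0L) {
    cx_abort("No tracks to average.", "cx_validation_error")
  }
  if (length(tracks) == 1L) return(tracks[[1]])
  walk(tracks[-1], ~ stopifnot_same_shape(tracks[[1]], .x))
  if (length(unique(map_chr(tracks, "state"))) != 1L) {
    cx_abort("Tracks to average must share a normalization state.",
             "cx_validation_error")
  }
  out <- tracks[[1]]
  out$values <- lapply(names(out$values), function(chrom) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[chrom]])) / length(tracks)
  })
  names(out$values) <- names(tracks[[1]]$values)
  out
}
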