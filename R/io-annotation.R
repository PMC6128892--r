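#' Read gene models from BED or GFF3
#'
#' Parses a gene annotation into a tibble of gene models with a derived
#' transcription start site (TSS). Internal coordinates are uniformly 0-based
#' half-open; GFF3 input (1-based, closed) is converted on read. The TSS is
#' the 5' end of the gene in gene orientation: `start` for plus-strand genes
#' and `end - 1` (the last covered base) for minus-strand genes.
#'
#' @param path Path to a BED (>= 4 columns: chrom, start, end, name, and
#'   optionally score and strand) or GFF3 file. Format is chosen from the
#'   file extension unless `format` is given.
#' @param space A [genome_space()]; every feature must lie within one of its
#'   chromosomes.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @param feature_type GFF3 only: feature type to keep (default `"gene"`;
#'   if the file contains no such features, all features are used).
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, in file order.
#' @export
read_annotation <- function(path, space, format = c("auto", "bed", "gff3"),
                            feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cx_abort(sprintf("Annotation file not found: %s", path), "cx_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  genes <- if (format == "gff3") {
    read_genes_gff3(path, feature_type)
  } else {
    read_genes_bed(path)
  }
  validate_genes(genes, space)
}

read_genes_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = double(), end = double(), strand = character()))
  }
  if (ncol(raw) < 4L) {
    cx_abort("Gene BED needs at least 4 columns (chrom, start, end, name).",
             "cx_parse_error")
  }
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    cx_abort(sprintf("Malformed BED coordinates at line %d of %s.",
                     bad[1], path), "cx_parse_error")
  }
  strand <- if (ncol(raw) >= 6L) normalise_strand(raw[[6]], path) else
    rep("+", nrow(raw))
  tibble(gene_id = raw[[4]], chrom = raw[[1]],
         start = start, end = end, strand = strand)
}

read_genes_gff3 <- function(path, feature_type) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if ("type" %in% names(df) && any(df$type == feature_type)) {
    df <- df[df$type == feature_type, , drop = FALSE]
  }
  id <- if ("ID" %in% names(df)) as.character(df$ID) else
    if ("Name" %in% names(df)) as.character(df$Name) else
      sprintf("feature_%d", seq_len(nrow(df)))
  tibble(
    gene_id = id,
    chrom = as.character(df$seqnames),
    start = as.numeric(df$start) - 1,  # 1-based closed -> 0-based half-open
    end = as.numeric(df$end),
    strand = ifelse(as.character(df$strand) == "-", "-", "+")
  )
}

normalise_strand <- function(x, path) {
  x <- as.character(x)
  # tolerate the typographic minus occasionally found in hand-edited files
  x[x == "−"] <- "-"
  bad <- which(!x %in% c("+", "-", "."))
  if (length(bad) > 0L) {
    cx_abort(sprintf("Invalid strand '%s' at line %d of %s.",
                     x[bad[1]], bad[1], path), "cx_parse_error")
  }
  x[x == "."] <- "+"
  x
}

validate_genes <- function(genes, space) {
  bad <- which(!(genes$start < genes$end))
  if (length(bad) > 0L) {
    cx_abort(sprintf("Gene '%s' has start >= end.", genes$gene_id[bad[1]]),
             "cx_validation_error")
  }
  check_chroms_known(genes$chrom, space, "Gene feature(s)")
  beyond <- which(genes$end > space$chrom_sizes[genes$chrom] | genes$start < 0)
  if (length(beyond) > 0L) {
    cx_abort(sprintf("Gene '%s' extends beyond its chromosome.",
                     genes$gene_id[beyond[1]]), "cx_validation_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    cx_abort(sprintf("Duplicate gene_id '%s' in annotation.", dup),
             "cx_validation_error")
  }
  genes |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1)) |>
    select("gene_id", "chrom", "start", "end", "strand", "tss")
}

#' Write gene models to BED6 or GFF3
#'
#' The inverse of [read_annotation()]: internal 0-based half-open coordinates
#' are written unchanged for BED and converted to 1-based closed for GFF3, so
#' a read/write round trip preserves the on-disk coordinates of either format.
#'
#' @param genes Tibble of gene models as returned by [read_annotation()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand"),
                "Gene table")
  if (format == "bed") {
    readr::write_tsv(
      tibble(genes$chrom, format_bp(genes$start), format_bp(genes$end),
             genes$gene_id, 0L, genes$strand),
      path, col_names = FALSE
    )
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
      strand = genes$strand
    )
    gr$ID <- genes$gene_id
    gr$type <- "gene"
    gr$source <- "chromexpress"
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
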