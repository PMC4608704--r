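#' Genomic intervals
#'
#' All loci in this package use a single convention: 0-based, half-open
#' `[start, end)` intervals, so `length = end - start`. External formats that
#' use other conventions (VCF is 1-based; MAF is strand-relative) are
#' converted at the parsing boundary.
#'
#' @param chrom character vector of sequence names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `end > start`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param id optional identifier column.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `id` if given), of class `c("genomic_intervals", "data.frame")`.
#' @export
gintervals <- function(chrom, start, end, strand = ".", id = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L)) {
    stopf("interval starts must be non-negative integers")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stopf("interval end must exceed start (violated at row %d: [%d,%d))",
          bad, start[bad], end[bad])
  }
  if (!all(strand %in% c("+", "-", "."))) stopf("strand must be +, - or .")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- as.character(id)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

# Convert 0-based half-open intervals to GRanges (1-based closed) for
# overlap arithmetic; strand is dropped (overlaps are strand-blind here).
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

interval_length <- function(x) x$end - x$start

#' Read a BED6 file of loci
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#'
#' @param path BED file with at least chrom/start/end/name columns.
#' @return `genomic_intervals` data frame with an `id` column.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4L) stopf("BED file %s needs >= 4 columns", path)
  strand <- if (ncol(df) >= 6L) df[[6]] else "."
  gintervals(df[[1]], df[[2]], df[[3]], strand = strand, id = df[[4]])
}

#' Write loci as BED6
#'
#' @param x `genomic_intervals` with an `id` column.
#' @param path output path.
#' @param score numeric score column (default 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, score = 0) {
  stopifnot(!is.null(x$id))
  out <- data.frame(x$chrom, x$start, x$end, x$id,
                    rep_len(score, nrow(x)),
                    ifelse(x$strand == ".", ".", x$strand))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
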