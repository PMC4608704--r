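#' Read a read-count matrix
#'
#' Loci in rows, samples in columns, tab-separated with a header row and
#' locus ids in the first column. Counts are expected to be the product of
#' upstream unique/concordant alignment filtering (mapping quality >= 50);
#' the reader checks shape and non-negativity only, and requires the caller
#' to assert the upstream filter via `filtered`.
#'
#' @param path TSV path.
#' @param filtered logical flag asserting that counts were produced under
#'   the unique/concordant MAPQ >= 50 ingestion contract.
#' @return integer matrix (loci x samples).
#' @export
read_counts <- function(path, filtered = TRUE) {
  if (!isTRUE(filtered)) {
    stopf("count matrices must be declared pre-filtered (filtered = TRUE)")
  }
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stopf("negative count in %s", path)
  m
}

#' Write a read-count matrix
#'
#' @param counts integer matrix (loci x samples) with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(locus = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group labels
#'
#' Two-column TSV: sample id, group label.
#'
#' @param path TSV path.
#' @return named character vector (sample -> group).
#' @export
read_sample_groups <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "sample")) df <- df[-1, , drop = FALSE]
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write an RDV table
#'
#' One row per retrocopy x deletion record. Per-population deletion allele
#' frequencies are printed as percentages with two decimals (so a frequency
#' of 0.1124 prints as `11.24`). Rows are ordered by retrocopy id, then
#' deletion id.
#'
#' @param records data.frame from [build_rdv_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdv_table <- function(records, path) {
  pops <- attr(records, "populations")
  if (is.null(pops)) {
    pops <- setdiff(colnames(records),
                    c("retrocopy_id", "deletion_id", "overlap_bp",
                      "indel_length_bp", "n_populations_affected",
                      "spread_category"))
  }
  records <- records[order(records$retrocopy_id, records$deletion_id), ,
                     drop = FALSE]
  out <- data.frame(
    retrocopy_id = records$retrocopy_id,
    deletion_id = records$deletion_id,
    indel_length_bp = records$indel_length_bp,
    overlap_bp = records$overlap_bp,
    stringsAsFactors = FALSE
  )
  for (p in pops) {
    out[[p]] <- ifelse(is.na(records[[p]]), "NA",
                       sprintf("%.2f", 100 * records[[p]]))
  }
  out$n_populations_affected <- records$n_populations_affected
  out$spread_category <- records$spread_category
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RDV table written by [write_rdv_table()]
#'
#' Percent columns are converted back to fractions.
#'
#' @param path TSV path.
#' @return data.frame with frequencies on the 0-1 scale and a
#'   `populations` attribute.
#' @export
read_rdv_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  fixed <- c("retrocopy_id", "deletion_id", "overlap_bp", "indel_length_bp",
             "n_populations_affected", "spread_category")
  pops <- setdiff(colnames(df), fixed)
  for (p in pops) df[[p]] <- suppressWarnings(as.numeric(df[[p]])) / 100
  attr(df, "populations") <- pops
  df
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample`, `target`, `ct_target`, `ct_reference`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "target", "ct_target", "ct_reference")
  if (!all(need %in% colnames(df))) {
    stopf("Ct table must have columns: %s", paste(need, collapse = ", "))
  }
  df
}

#' Read qPCR fluorescence curves
#'
#' TSV with columns `well`, `cycle`, `fluorescence`.
#'
#' @param path TSV path.
#' @return list of numeric fluorescence vectors (cycle order), one per well.
#' @export
read_fluorescence <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(split(df, df$well), function(d) d$fluorescence[order(d$cycle)])
}
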