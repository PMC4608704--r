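#' Read a FASTA file
#'
#' @param path FASTA file (nucleotide or protein).
#' @return named character vector, uppercased, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stopf("empty FASTA record: %s", ids[nchar(seqs) == 0L][1])
  }
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) == 0L || !is.null(names(seqs)))
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
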