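#' Simulate error-bearing short reads over template sequences
#'
#' Reads are placed uniformly to reach the target coverage, drawn from both
#' strands, with independent per-base substitution errors.
#'
#' @param sequences named character vector of templates.
#' @param read_length read length (must not exceed the shortest template).
#' @param coverage target fold coverage per template.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return named character vector of reads; names record the template,
#'   0-based start and strand (`<template>_<i>_<start>_<strand>`).
#' @export
simulate_reads <- function(sequences, read_length = 100L, coverage = 20,
                           error_rate = 0, seed = 1L) {
  stopifnot(read_length <= min(nchar(sequences)))
  set.seed(seed)
  reads <- character()
  for (sid in names(sequences)) {
    s <- sequences[[sid]]
    L <- nchar(s)
    n <- ceiling(coverage * L / read_length)
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      r <- substr(s, starts[i] + 1L, starts[i] + read_length)
      if (strands[i] == "-") r <- revcomp(r)
      if (error_rate > 0) r <- mutate_dna(r, error_rate)
      reads[sprintf("%s_%d_%d_%s", sid, i, starts[i], strands[i])] <- r
    }
  }
  reads
}
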