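#' @import methods
#' @importFrom stats median rbinom rnbinom rnorm runif setNames var pnorm
#'   p.adjust dhyper quantile lm coef rpois complete.cases
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Draws bases uniformly and independently; uses the current RNG state.
#'
#' @param n sequence length in bp.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Translate a DNA sequence
#'
#' Translates the first reading frame; the sequence is truncated to a whole
#' number of codons. Stop codons appear as `*`.
#'
#' @param dna character scalar (ACGT).
#' @return amino-acid string.
#' @export
translate_dna <- function(dna) {
  n <- (nchar(dna) %/% 3L) * 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, n)),
    if.fuzzy.codon = "solve"
  ))
}

# Point-mutate a DNA string at a fixed per-site substitution rate.
mutate_dna <- function(dna, rate) {
  if (rate <= 0) return(dna)
  bases <- strsplit(dna, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

# Deterministic child seed: keeps derived seeds positive and below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
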