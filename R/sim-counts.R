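#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Counts are drawn NB with mean `baseline * size_factor * 2^(log2fc * I)`
#' where `I` indicates the second group, and variance
#' `mu + dispersion * mu^2`. A `dispersion` of zero falls back to Poisson.
#'
#' @param n_loci number of loci.
#' @param groups named character vector (sample -> group label); exactly two
#'   distinct labels, the first level is the reference group.
#' @param size_factors named per-sample factors; drawn uniform(0.7, 1.3)
#'   when `NULL`.
#' @param dispersion NB dispersion (alpha), `>= 0`.
#' @param de_fraction fraction of loci planted as differentially expressed.
#' @param log2fc absolute planted log2 fold change (sign randomised).
#' @param baseline mean count scale; scalar or range of two values.
#' @param seed RNG seed.
#' @return list with `counts` (integer matrix), `truth` (data.frame locus /
#'   log2fc / dispersion), and `size_factors`.
#' @export
simulate_counts_nb <- function(n_loci, groups, size_factors = NULL,
                               dispersion = 0.1, de_fraction = 0,
                               log2fc = 2, baseline = c(100, 1000),
                               seed = 1L) {
  stopifnot(dispersion >= 0, length(unique(groups)) == 2L,
            all(table(groups) >= 2L))
  set.seed(seed)
  samples <- names(groups)
  if (is.null(size_factors)) {
    size_factors <- setNames(runif(length(samples), 0.7, 1.3), samples)
  }
  lev <- unique(unname(groups))
  ind <- as.numeric(groups == lev[2])
  if (length(baseline) == 1L) baseline <- rep(baseline, 2L)
  base <- runif(n_loci, baseline[1], baseline[2])
  lfc <- numeric(n_loci)
  n_de <- round(de_fraction * n_loci)
  if (n_de > 0L) {
    de_idx <- sample.int(n_loci, n_de)
    lfc[de_idx] <- log2fc * sample(c(-1, 1), n_de, replace = TRUE)
  }
  counts <- matrix(0L, n_loci, length(samples),
                   dimnames = list(sprintf("locus%05d", seq_len(n_loci)),
                                   samples))
  for (j in seq_along(samples)) {
    mu <- base * size_factors[j] * 2^(lfc * ind[j])
    counts[, j] <- if (dispersion > 0) {
      rnbinom(n_loci, mu = mu, size = 1 / dispersion)
    } else {
      rpois(n_loci, lambda = mu)
    }
  }
  truth <- data.frame(locus = rownames(counts), log2fc = lfc,
                      dispersion = dispersion, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, size_factors = size_factors)
}
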