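#' Simulate diploid deletion genotypes at planted population frequencies
#'
#' Each individual's two alleles are drawn independently as
#' Bernoulli(f_pop) — Hardy-Weinberg proportions within populations.
#'
#' @param deletions `genomic_intervals` with an `id` column, one row per
#'   deletion locus.
#' @param panel named vector from [read_panel()].
#' @param frequencies numeric matrix of planted deletion allele frequencies
#'   in `[0,1]`, rows = deletion ids, columns = population codes (must cover
#'   every population in the panel).
#' @param seed RNG seed.
#' @return list with `deletions` (list of `deletion_variant`) and `truth`
#'   (the frequency matrix, as planted).
#' @export
simulate_population_genotypes <- function(deletions, panel, frequencies,
                                          seed = 1L) {
  set.seed(seed)
  pops <- unique(unname(panel))
  unknown <- setdiff(colnames(frequencies), pops)
  if (length(unknown) > 0L) {
    stopf("unknown population in frequencies: %s", unknown[1])
  }
  if (!all(pops %in% colnames(frequencies))) {
    stopf("frequencies must cover every panel population")
  }
  stopifnot(all(frequencies >= 0 & frequencies <= 1))
  inds <- names(panel)
  out <- vector("list", nrow(deletions))
  for (i in seq_len(nrow(deletions))) {
    did <- deletions$id[i]
    f <- frequencies[did, ][panel[inds]]
    gmat <- cbind(a1 = rbinom(length(inds), 1L, f),
                  a2 = rbinom(length(inds), 1L, f))
    rownames(gmat) <- inds
    out[[i]] <- structure(
      list(id = did, locus = deletions[i, , drop = FALSE], genotypes = gmat),
      class = "deletion_variant")
  }
  list(deletions = out, truth = frequencies)
}
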