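#' Intersect retrocopy loci with deletion variants
#'
#' A deletion is paired with a retrocopy when the interval intersection
#' removes at least `min_overlap_bp` of the retrocopy sequence (default
#' 100 bp); strand is ignored.
#'
#' @param retrocopies `genomic_intervals` with `id`.
#' @param deletions list of `deletion_variant` objects.
#' @param min_overlap_bp minimum intersection length.
#' @return data.frame with `retrocopy_id`, `deletion_id`, `overlap_bp`.
#' @export
overlap_deletions <- function(retrocopies, deletions, min_overlap_bp = 100L) {
  empty <- data.frame(retrocopy_id = character(), deletion_id = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(retrocopies) == 0L || length(deletions) == 0L) return(empty)
  del_loci <- do.call(rbind, lapply(deletions, function(d) d$locus))
  del_loci$id <- vapply(deletions, function(d) d$id, character(1))
  gr_r <- intervals_to_granges(retrocopies)
  gr_d <- intervals_to_granges(del_loci)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_d)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(retrocopies$end[qi], del_loci$end[si]) -
    pmax(retrocopies$start[qi], del_loci$start[si])
  keep <- ov >= min_overlap_bp
  out <- data.frame(retrocopy_id = retrocopies$id[qi][keep],
                    deletion_id = del_loci$id[si][keep],
                    overlap_bp = as.integer(ov[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$retrocopy_id, out$deletion_id), , drop = FALSE]
}

#' Per-population deletion allele frequency
#'
#' Frequency = deletion alleles / non-missing alleles within each
#' population. Missing genotypes are excluded from both numerator and
#' denominator; a population with zero non-missing alleles is `NA`.
#'
#' @param deletion a `deletion_variant`.
#' @param panel named vector (individual -> population).
#' @return named numeric vector over the panel's populations.
#' @export
allele_frequency <- function(deletion, panel) {
  pops <- sort(unique(unname(panel)))
  g <- deletion$genotypes
  out <- setNames(rep(NA_real_, length(pops)), pops)
  pop_of <- panel[rownames(g)]
  for (p in pops) {
    al <- as.vector(g[which(pop_of == p), , drop = FALSE])
    al <- al[!is.na(al)]
    if (length(al) > 0L) out[p] <- sum(al) / length(al)
  }
  out
}

#' Categorize the population spread of a deletion
#'
#' Bins follow the reporting convention for 14 populations: affected in one
#' population only (`population_specific`), 2-5, 6-8, 9-13, or all. A
#' population is affected when its deletion allele frequency is above zero,
#' however small.
#'
#' @param frequencies named numeric vector of per-population frequencies.
#' @param n_populations_total number of populations analysed.
#' @return list with `n_affected` and `spread_category`.
#' @export
categorize_spread <- function(frequencies, n_populations_total = 14L) {
  n <- sum(frequencies > 0, na.rm = TRUE)
  cat <- if (n == 0L) "none"
  else if (n == n_populations_total) "all"
  else if (n == 1L) "population_specific"
  else if (n <= 5L) "2-5"
  else if (n <= 8L) "6-8"
  else "9-13"
  list(n_affected = as.integer(n), spread_category = cat)
}

#' Build the RDV table
#'
#' One record per (retrocopy, deletion) pair surviving the 100-bp overlap
#' rule, with per-population deletion allele frequencies and the spread
#' category. A retrocopy hit by several deletions yields several records,
#' so the number of records is at least the number of distinct retrocopies.
#'
#' @param retrocopies `genomic_intervals` with `id`.
#' @param deletions list of `deletion_variant` objects.
#' @param panel named vector (individual -> population).
#' @param min_overlap_bp minimum intersection length (default 100).
#' @return data.frame with one frequency column per population (0-1 scale)
#'   and a `populations` attribute; rows ordered by retrocopy id then
#'   deletion id.
#' @export
build_rdv_table <- function(retrocopies, deletions, panel,
                            min_overlap_bp = 100L) {
  pops <- sort(unique(unname(panel)))
  pairs <- overlap_deletions(retrocopies, deletions, min_overlap_bp)
  if (nrow(pairs) == 0L) {
    out <- data.frame(retrocopy_id = character(), deletion_id = character(),
                      overlap_bp = integer(), indel_length_bp = integer(),
                      stringsAsFactors = FALSE)
    for (p in pops) out[[p]] <- numeric()
    out$n_populations_affected <- integer()
    out$spread_category <- character()
    attr(out, "populations") <- pops
    return(out)
  }
  del_by_id <- setNames(deletions, vapply(deletions, `[[`, character(1), "id"))
  freq_cache <- lapply(del_by_id, allele_frequency, panel = panel)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    did <- pairs$deletion_id[i]
    f <- freq_cache[[did]]
    spread <- categorize_spread(f, length(pops))
    row <- data.frame(retrocopy_id = pairs$retrocopy_id[i],
                      deletion_id = did,
                      overlap_bp = pairs$overlap_bp[i],
                      indel_length_bp = interval_length(del_by_id[[did]]$locus),
                      stringsAsFactors = FALSE)
    for (p in pops) row[[p]] <- unname(f[p])
    row$n_populations_affected <- spread$n_affected
    row$spread_category <- spread$spread_category
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$retrocopy_id, out$deletion_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- pops
  out
}

#' Summarize spread categories of an RDV table
#'
#' @param rdv_table data.frame from [build_rdv_table()].
#' @return named integer vector of record counts per spread category.
#' @export
summarize_spread <- function(rdv_table) {
  cats <- c("population_specific", "2-5", "6-8", "9-13", "all", "none")
  tab <- table(factor(rdv_table$spread_category, levels = cats))
  setNames(as.integer(tab), cats)
}
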