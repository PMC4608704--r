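#' Default retrocopy acceptance thresholds
#'
#' A candidate alignment is accepted as a retrocopy when it spans at least
#' `min_span_bp` on the genomic sequence, has alignment identity and parent
#' protein coverage strictly greater than 50%, and at least two parental
#' introns are inferred as lost.
#'
#' @param min_span_bp minimum genomic span (bp).
#' @param min_identity_pct identity threshold (strict, percent).
#' @param min_coverage_pct protein coverage threshold (strict, percent).
#' @param min_introns_lost minimum inferred lost introns.
#' @param max_junction_gap_bp maximum genomic gap across a collapsed exon
#'   junction for the intron to count as lost.
#' @param min_flank_aa aligned parent residues required on each side of a
#'   junction before it is scored.
#' @return named list of thresholds.
#' @export
retrocopy_thresholds <- function(min_span_bp = 150L,
                                 min_identity_pct = 50,
                                 min_coverage_pct = 50,
                                 min_introns_lost = 2L,
                                 max_junction_gap_bp = 30L,
                                 min_flank_aa = 10L) {
  list(min_span_bp = min_span_bp, min_identity_pct = min_identity_pct,
       min_coverage_pct = min_coverage_pct,
       min_introns_lost = min_introns_lost,
       max_junction_gap_bp = max_junction_gap_bp,
       min_flank_aa = min_flank_aa)
}

#' Count parental introns lost in a translated alignment
#'
#' A parental intron counts as lost when the alignment covers at least
#' `min_flank_aa` parent residues immediately on both sides of the exon
#' junction and the genomic distance between the codons flanking the
#' junction is at most `max_junction_gap_bp` (i.e. the junction is collapsed
#' on the genomic copy). A retained intron leaves a large genomic gap or an
#' unalignable far side, so it does not count.
#'
#' @param alignment `translated_alignment` from [translated_align()].
#' @param model parental `gene_model` (CDS exon structure).
#' @param max_junction_gap_bp,min_flank_aa see [retrocopy_thresholds()].
#' @return integer count of lost introns (0 for single-exon parents).
#' @export
infer_lost_introns <- function(alignment, model,
                               max_junction_gap_bp = 30L,
                               min_flank_aa = 10L) {
  if (is.null(model$cds) || nrow(model$cds) < 2L) return(0L)
  if (is.null(alignment)) return(0L)
  lens <- interval_length(model$cds)
  if (model$strand == "-") lens <- rev(lens)
  cuts <- cumsum(lens)[-length(lens)]     # junction positions in CDS nt
  aligned <- alignment$pairs$p_res
  lost <- 0L
  for (c_nt in cuts) {
    # last codon fully before and first codon fully after the junction
    # (a codon straddling the junction is skipped, expected span 3 bp)
    rA <- c_nt %/% 3L
    rB <- rA + if (c_nt %% 3L == 0L) 1L else 2L
    left_win <- seq(rA - min_flank_aa + 1L, rA)
    right_win <- seq(rB, rB + min_flank_aa - 1L)
    if (left_win[1] < 1L ||
        right_win[length(right_win)] > alignment$protein_len) next
    if (!all(left_win %in% aligned) || !all(right_win %in% aligned)) next
    gA <- alignment$pairs[match(rA, aligned), ]
    gB <- alignment$pairs[match(rB, aligned), ]
    d <- if (alignment$strand == "+") gB$g_start - gA$g_end
         else gA$g_start - gB$g_end
    extra <- d - 3L * (rB - rA - 1L)
    if (extra >= 0L && extra <= max_junction_gap_bp) lost <- lost + 1L
  }
  lost
}

#' Test whether a retrocopy has a conserved open reading frame
#'
#' Globally aligns the retrocopy to the parental CDS; the ORF is conserved
#' when every gap run in either sequence has a length divisible by three (no
#' frameshift) and translating the retrocopy in the parent-anchored frame
#' yields no internal stop codon over the aligned region (a stop aligned to
#' the parent's terminal stop codon is allowed).
#'
#' @param retro_dna retrocopy sequence (mRNA orientation).
#' @param parent_cds_dna parental CDS sequence (may include the terminal
#'   stop codon).
#' @return logical.
#' @export
conserved_orf <- function(retro_dna, parent_cds_dna) {
  stopifnot(nchar(retro_dna) > 0L, nchar(parent_cds_dna) > 0L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(retro_dna), Biostrings::DNAString(parent_cds_dna),
    type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  rchars <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  pchars <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  for (chars in list(rchars, pchars)) {
    runs <- rle(chars == "-")
    if (any(runs$values & runs$lengths %% 3L != 0L)) return(FALSE)
  }
  both <- which(rchars != "-" & pchars != "-")
  if (length(both) == 0L) return(FALSE)
  core <- both[1]:both[length(both)]
  parent_before <- sum(pchars[seq_len(both[1] - 1L)] != "-")
  skip <- (3L - parent_before %% 3L) %% 3L
  retro_core <- paste(rchars[core][rchars[core] != "-"], collapse = "")
  if (nchar(retro_core) <= skip + 2L) return(FALSE)
  aa <- translate_dna(substr(retro_core, skip + 1L, nchar(retro_core)))
  body <- substr(aa, 1L, nchar(aa) - 1L)
  !grepl("*", body, fixed = TRUE)
}

#' Classify a translated alignment as a retrocopy call or rejection
#'
#' Applies the acceptance rule: genomic span >= 150 bp, identity > 50%,
#' protein coverage > 50% (both strict), and >= 2 introns lost. The
#' rejection reason names the first failed criterion.
#'
#' @param alignment `translated_alignment` (or `NULL`).
#' @param model parental `gene_model`.
#' @param thresholds list from [retrocopy_thresholds()].
#' @return list with `accepted` (logical) and either `call` (one-row
#'   data.frame) or `reason` (character).
#' @export
classify_retrocopy <- function(alignment, model,
                               thresholds = retrocopy_thresholds()) {
  th <- thresholds
  if (is.null(alignment)) {
    return(list(accepted = FALSE, reason = "no_alignment"))
  }
  span <- alignment$g_end - alignment$g_start
  if (span < th$min_span_bp) {
    return(list(accepted = FALSE, reason = "min_span"))
  }
  if (!(alignment$identity > th$min_identity_pct)) {
    return(list(accepted = FALSE, reason = "min_identity"))
  }
  if (!(alignment$coverage > th$min_coverage_pct)) {
    return(list(accepted = FALSE, reason = "min_coverage"))
  }
  introns_lost <- infer_lost_introns(alignment, model,
                                     th$max_junction_gap_bp,
                                     th$min_flank_aa)
  if (introns_lost < th$min_introns_lost) {
    return(list(accepted = FALSE, reason = "min_introns_lost"))
  }
  call <- data.frame(
    parent_gene = model$gene_id, transcript = model$transcript_id,
    g_start = alignment$g_start, g_end = alignment$g_end,
    strand = alignment$strand, genomic_span_bp = span,
    identity_pct = alignment$identity,
    protein_coverage_pct = alignment$coverage,
    introns_lost = introns_lost, score = alignment$score,
    stringsAsFactors = FALSE)
  list(accepted = TRUE, call = call)
}

#' Call retrocopies of a proteome on target sequences
#'
#' For every (protein, target) pair the best translated alignment is
#' classified; accepted calls that overlap on the same target are reduced to
#' the highest-scoring parent (ties broken by identity, then gene id).
#' When `parent_cds` sequences are supplied the ORF-conservation flag is
#' computed for each call.
#'
#' @param models list of parental `gene_model`s carrying `protein` (and used
#'   for intron-junction structure).
#' @param targets named character vector of target DNA sequences.
#' @param thresholds list from [retrocopy_thresholds()].
#' @param parent_cds optional named vector (transcript id -> CDS sequence)
#'   enabling the `orf_conserved` column.
#' @return data.frame of retrocopy calls, ordered by target then position,
#'   with 0-based half-open `g_start`/`g_end` on the target and a
#'   `retrocopy_id` column.
#' @export
call_retrocopies <- function(models, targets,
                             thresholds = retrocopy_thresholds(),
                             parent_cds = NULL) {
  calls <- list()
  for (tname in names(targets)) {
    tseq <- targets[[tname]]
    if (nchar(tseq) < 60L) next
    for (m in models) {
      if (is.null(m$protein) || nchar(m$protein) < 20L) next
      al <- translated_align(m$protein, tseq)
      res <- classify_retrocopy(al, m, thresholds)
      if (!res$accepted) next
      row <- res$call
      row$target <- tname
      if (!is.null(parent_cds) && m$transcript_id %in% names(parent_cds)) {
        retro <- substr(tseq, row$g_start + 1L, row$g_end)
        if (row$strand == "-") retro <- revcomp(retro)
        row$orf_conserved <- conserved_orf(retro,
                                           parent_cds[[m$transcript_id]])
      }
      calls[[length(calls) + 1L]] <- row
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(retrocopy_id = character(), target = character(),
                      g_start = integer(), g_end = integer(),
                      parent_gene = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, calls)
  kept <- list()
  for (tname in sort(unique(df$target))) {
    sub <- df[df$target == tname, , drop = FALSE]
    sub <- sub[order(sub$g_start, sub$g_end), , drop = FALSE]
    # connected runs of mutually overlapping calls -> best parent wins
    grp <- integer(nrow(sub)); cur <- 0L; cur_end <- -1L
    for (i in seq_len(nrow(sub))) {
      if (sub$g_start[i] >= cur_end) cur <- cur + 1L
      cur_end <- max(cur_end, sub$g_end[i])
      grp[i] <- cur
    }
    for (g in unique(grp)) {
      cand <- sub[grp == g, , drop = FALSE]
      cand <- cand[order(-cand$score, -cand$identity_pct,
                         cand$parent_gene), , drop = FALSE]
      kept[[length(kept) + 1L]] <- cand[1L, , drop = FALSE]
    }
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$target, out$g_start), , drop = FALSE]
  out$retrocopy_id <- sprintf("rcall_%s_%d", out$target, out$g_start)
  rownames(out) <- NULL
  out[, c("retrocopy_id", "target", "g_start", "g_end", "strand",
          "parent_gene", "transcript", "genomic_span_bp", "identity_pct",
          "protein_coverage_pct", "introns_lost", "score",
          intersect("orf_conserved", colnames(out)))]
}
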