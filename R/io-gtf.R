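#' Read gene models from a GTF file
#'
#' Parses `exon` and `CDS` features grouped by `transcript_id`. Coordinates
#' are converted from GTF's 1-based closed convention to 0-based half-open.
#' Exons are stored sorted by genomic coordinate; for minus-strand genes the
#' mRNA-order exon indices run from the genomically last exon backwards.
#'
#' @param path GTF file.
#' @param genome optional named character vector of chromosome sequences;
#'   needed to derive mRNA/CDS sequence and the protein.
#' @param proteins optional named character vector (transcript id ->
#'   protein); when absent and `genome` is given, the protein is derived by
#'   translating the CDS.
#' @return list of `gene_model` objects: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `exons` (genomic order), `cds`, `n_introns`, and,
#'   when derivable, `mrna` and `protein`.
#' @export
read_gene_models <- function(path, genome = NULL, proteins = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  tx <- as.character(meta$transcript_id)
  type <- as.character(meta$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; tx <- tx[keep]; type <- type[keep]
  models <- list()
  for (t in unique(tx)) {
    sel <- tx == t
    g <- gr[sel]
    ty <- type[sel]
    exon_gr <- g[ty == "exon"]
    cds_gr <- g[ty == "CDS"]
    if (length(exon_gr) == 0L) exon_gr <- cds_gr
    ord <- order(GenomicRanges::start(exon_gr))
    exon_gr <- exon_gr[ord]
    strand <- as.character(GenomicRanges::strand(exon_gr))[1]
    chrom <- as.character(GenomicRanges::seqnames(exon_gr))[1]
    st <- GenomicRanges::start(exon_gr) - 1L
    en <- GenomicRanges::end(exon_gr)
    if (length(st) > 1L && any(st[-1] < en[-length(en)])) {
      stopf("overlapping exons in transcript %s", t)
    }
    exons <- gintervals(rep(chrom, length(st)), st, en, strand)
    cds <- NULL
    if (length(cds_gr) > 0L) {
      cord <- order(GenomicRanges::start(cds_gr))
      cds <- gintervals(rep(chrom, length(cds_gr)),
                        GenomicRanges::start(cds_gr)[cord] - 1L,
                        GenomicRanges::end(cds_gr)[cord], strand)
      if (sum(interval_length(cds)) %% 3L != 0L) {
        stopf("CDS length of transcript %s is not divisible by 3", t)
      }
    }
    gene_id <- as.character(S4Vectors::mcols(g)$gene_id)[1]
    model <- structure(
      list(gene_id = gene_id %||% t, transcript_id = t, chrom = chrom,
           strand = strand, exons = exons, cds = cds,
           n_introns = nrow(exons) - 1L, mrna = NULL, protein = NULL),
      class = "gene_model"
    )
    if (!is.null(genome) && !is.null(genome[chrom]) && !is.na(genome[chrom])) {
      model$mrna <- spliced_sequence(genome[[chrom]], exons, strand)
      if (!is.null(cds)) {
        cds_seq <- spliced_sequence(genome[[chrom]], cds, strand)
        prot <- translate_dna(cds_seq)
        model$protein <- sub("\\*$", "", prot)
      }
    }
    if (!is.null(proteins) && t %in% names(proteins)) {
      model$protein <- unname(proteins[t])
    }
    models[[t]] <- model
  }
  unname(models)
}

# Concatenate exon sequences in mRNA order (reverse-complемented as a whole
# for minus-strand genes).
spliced_sequence <- function(chrom_seq, exons, strand) {
  pieces <- substring(chrom_seq, exons$start + 1L, exons$end)
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Write gene models as GTF
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character()
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    feat <- function(iv, type) {
      sprintf("%s\tretrodup\t%s\t%d\t%d\t.\t%s\t.\t%s",
              iv$chrom, type, iv$start + 1L, iv$end, m$strand, attrs)
    }
    lines <- c(lines, feat(m$exons, "exon"))
    if (!is.null(m$cds)) lines <- c(lines, feat(m$cds, "CDS"))
  }
  writeLines(lines, path)
  invisible(path)
}
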