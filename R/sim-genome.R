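#' Simulate a genome with multi-exon protein-coding genes
#'
#' Builds a random genome and places non-overlapping genes on it. Every gene
#' is fully coding (CDS = exons), starts with ATG, ends with a stop codon and
#' translates without internal stops. Gene strands are drawn at random, so
#' minus-strand coordinate handling is exercised downstream.
#'
#' @param n_genes number of genes to place.
#' @param exons_per_gene_range integer range for exon counts.
#' @param genome_length total genome length (single chromosome `chr1`).
#' @param seed RNG seed; identical seeds give identical output.
#' @param exon_bp_range,intron_bp_range ranges for exon/intron lengths (bp).
#' @param min_gap_bp minimum intergenic gap.
#' @return list with `genome` (named character vector), `models` (list of
#'   `gene_model`), `proteins` (named by transcript id).
#' @export
simulate_genome_with_genes <- function(n_genes,
                                       exons_per_gene_range = c(3L, 5L),
                                       genome_length = 100000L,
                                       seed = 1L,
                                       exon_bp_range = c(90L, 240L),
                                       intron_bp_range = c(60L, 200L),
                                       min_gap_bp = 100L) {
  set.seed(seed)
  genome <- random_dna(genome_length)
  models <- list()
  proteins <- character()
  cursor <- min_gap_bp
  for (g in seq_len(n_genes)) {
    n_ex <- exons_per_gene_range[1] +
      sample.int(exons_per_gene_range[2] - exons_per_gene_range[1] + 1L, 1L) - 1L
    exon_len <- sample(seq(exon_bp_range[1], exon_bp_range[2]), n_ex,
                       replace = TRUE)
    total <- sum(exon_len)
    exon_len[n_ex] <- exon_len[n_ex] + (3L - total %% 3L) %% 3L
    total <- sum(exon_len)
    n_codons <- total %/% 3L
    codons <- random_codons(n_codons - 2L)
    cds_seq <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    intron_len <- if (n_ex > 1L) {
      sample(seq(intron_bp_range[1], intron_bp_range[2]), n_ex - 1L,
             replace = TRUE)
    } else integer()
    introns <- vapply(intron_len, function(L) {
      paste0("GT", random_dna(L - 4L), "AG")
    }, character(1))
    # gene sequence in mRNA orientation
    pieces <- character()
    off <- 0L
    for (i in seq_len(n_ex)) {
      pieces <- c(pieces, substr(cds_seq, off + 1L, off + exon_len[i]))
      off <- off + exon_len[i]
      if (i < n_ex) pieces <- c(pieces, introns[i])
    }
    gene_seq <- paste(pieces, collapse = "")
    span <- nchar(gene_seq)
    start <- cursor
    if (start + span + min_gap_bp > genome_length) {
      stopf("cannot place gene %d: genome_length %d too small", g,
            genome_length)
    }
    strand <- sample(c("+", "-"), 1L)
    genomic_seq <- if (strand == "-") revcomp(gene_seq) else gene_seq
    genome <- paste0(substr(genome, 1L, start),
                     genomic_seq,
                     substr(genome, start + span + 1L, genome_length))
    # exon intervals in genomic coordinates (sorted by position)
    mrna_starts <- cumsum(c(0L, exon_len[-n_ex] + intron_len)) # oriented
    ex_start_or <- mrna_starts
    ex_end_or <- mrna_starts + exon_len
    if (strand == "+") {
      gs <- start + ex_start_or
      ge <- start + ex_end_or
    } else {
      gs <- start + span - ex_end_or
      ge <- start + span - ex_start_or
      ord <- order(gs); gs <- gs[ord]; ge <- ge[ord]
    }
    tid <- sprintf("tx%03d", g)
    exons <- gintervals(rep("chr1", n_ex), gs, ge, strand)
    protein <- sub("\\*$", "", translate_dna(cds_seq))
    models[[tid]] <- structure(
      list(gene_id = sprintf("gene%03d", g), transcript_id = tid,
           chrom = "chr1", strand = strand, exons = exons, cds = exons,
           n_introns = n_ex - 1L, mrna = cds_seq, protein = protein),
      class = "gene_model")
    proteins[tid] <- protein
    cursor <- start + span + min_gap_bp +
      sample.int(max(1L, min_gap_bp), 1L)
  }
  list(genome = c(chr1 = genome), models = unname(models),
       proteins = proteins)
}

# Random codons excluding stop codons.
random_codons <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- random_dna(3L)
      if (!cod %in% stops) break
    }
    out[i] <- cod
  }
  out
}

# Exon and intron sequences of a gene in mRNA orientation.
gene_oriented_parts <- function(model, chrom_seq) {
  ex <- model$exons
  gene_seq <- substr(chrom_seq, min(ex$start) + 1L, max(ex$end))
  if (model$strand == "-") {
    gene_seq <- revcomp(gene_seq)
    loc_start <- max(ex$end) - ex$end
    loc_end <- max(ex$end) - ex$start
    ord <- order(loc_start)
  } else {
    loc_start <- ex$start - min(ex$start)
    loc_end <- ex$end - min(ex$start)
    ord <- order(loc_start)
  }
  loc_start <- loc_start[ord]; loc_end <- loc_end[ord]
  exons <- substring(gene_seq, loc_start + 1L, loc_end)
  n <- length(exons)
  introns <- if (n > 1L) {
    substring(gene_seq, loc_end[-n] + 1L, loc_start[-1L])
  } else character()
  list(exons = exons, introns = introns)
}

#' Simulate the retroposition of a gene
#'
#' Emulates reverse transcription of the gene's mRNA and reinsertion: the
#' retrocopy is the gene sequence with the 3'-most `n_introns_lost` introns
#' spliced out (remaining introns are retained), point-mutated at a fixed
#' per-site substitution rate, truncated from the 5' end, and inserted into
#' the supplied target sequence. With all introns lost, zero divergence and
#' no truncation the retrocopy equals the full mRNA.
#'
#' @param model `gene_model` of the parental gene.
#' @param target target DNA (character scalar) to insert into.
#' @param divergence per-site substitution rate, in `[0, 0.5]`.
#' @param n_introns_lost number of intron junctions spliced out
#'   (`<=` parent intron count).
#' @param truncate_frac fraction of the retrocopy removed from the 5' end.
#' @param seed RNG seed.
#' @param chrom_seq chromosome sequence holding the parent gene; defaults to
#'   the parent mRNA reconstruction (valid only when all introns are lost).
#' @param insert_at 0-based insertion offset in `target`; random if `NULL`.
#' @return list with `target` (modified sequence), `locus`
#'   (`genomic_intervals` row on the target, chrom `"target"`), `retro_seq`,
#'   and `truth` (parent id, divergence, introns lost, truncation, ORF-intact
#'   flag, and `too_short` warning flag when < 150 bp survive).
#' @export
retropose <- function(model, target, divergence = 0.05,
                      n_introns_lost = model$n_introns,
                      truncate_frac = 0, seed = 1L,
                      chrom_seq = NULL, insert_at = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.5,
            n_introns_lost <= model$n_introns)
  set.seed(seed)
  if (is.null(chrom_seq)) {
    if (n_introns_lost < model$n_introns) {
      stopf("chrom_seq is required when introns are retained")
    }
    spliced <- model$mrna
    parts <- NULL
  } else {
    parts <- gene_oriented_parts(model, chrom_seq)
  }
  k <- model$n_introns
  if (!is.null(parts)) {
    lost <- if (n_introns_lost > 0L) seq(k - n_introns_lost + 1L, k) else integer()
    pieces <- parts$exons[1L]
    for (j in seq_len(k)) {
      if (!(j %in% lost)) pieces <- c(pieces, parts$introns[j])
      pieces <- c(pieces, parts$exons[j + 1L])
    }
    spliced <- paste(pieces, collapse = "")
  }
  mutated <- mutate_dna(spliced, divergence)
  cut <- floor(truncate_frac * nchar(mutated))
  retro <- substr(mutated, cut + 1L, nchar(mutated))
  too_short <- nchar(retro) < 150L
  if (too_short) warnf("retrocopy of %s is only %d bp after truncation",
                       model$gene_id, nchar(retro))
  if (is.null(insert_at)) {
    insert_at <- sample.int(nchar(target) - 1L, 1L)
  }
  out_seq <- paste0(substr(target, 1L, insert_at), retro,
                    substr(target, insert_at + 1L, nchar(target)))
  locus <- gintervals("target", insert_at, insert_at + nchar(retro),
                      strand = "+", id = paste0("retro_", model$gene_id))
  orf_intact <- FALSE
  if (n_introns_lost == k && truncate_frac == 0) {
    aa <- translate_dna(retro)
    body <- substr(aa, 1L, nchar(aa) - 1L)
    orf_intact <- !grepl("*", body, fixed = TRUE)
  }
  truth <- list(parent = model$gene_id, transcript = model$transcript_id,
                locus = locus, divergence = divergence,
                introns_lost = n_introns_lost,
                truncate_frac = truncate_frac,
                orf_intact = orf_intact, too_short = too_short)
  list(target = out_seq, locus = locus, retro_seq = retro, truth = truth)
}
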