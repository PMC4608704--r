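# Alignment statistics between two sequences (best of forward and reverse
# complement): local alignment identity over gap-excluded columns, and the
# number of aligned columns.
align_stats <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  best <- NULL
  for (q in c(query, revcomp(query))) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    if (is.null(best) || Biostrings::score(al) > best$score) {
      qc <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
      sc <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
      both <- qc != "-" & sc != "-"
      best <- list(score = Biostrings::score(al),
                   cols = sum(both),
                   matches = sum(both & qc == sc),
                   s_start = Biostrings::start(Biostrings::subject(al)) - 1L,
                   s_end = Biostrings::end(Biostrings::subject(al)),
                   flipped = !identical(q, query))
    }
  }
  best$identity <- if (best$cols > 0) best$matches / best$cols else 0
  best
}

#' Greedy assembly of short reads into contigs
#'
#' A deterministic overlap assembler: reads (plus their reverse complements)
#' are deduplicated and sorted lexicographically, then each unused read
#' seeds a contig that is extended in both directions by the read with the
#' maximal exact suffix-prefix overlap of at least `min_overlap_bp`. Reads
#' contained in a finished contig are consumed. Contigs shorter than
#' `min_contig_len` are discarded and reverse-complement duplicates reduced
#' to the lexicographically smaller strand.
#'
#' @param reads character vector of uppercase DNA reads.
#' @param min_overlap_bp minimum exact overlap (default 31).
#' @param min_contig_len minimum contig length to report (default 500).
#' @return named character vector of contigs (`contig_1`, ...).
#' @export
assemble_contigs <- function(reads, min_overlap_bp = 31L,
                             min_contig_len = 500L) {
  if (length(reads) == 0L) return(setNames(character(), character()))
  reads <- toupper(unname(reads))
  uniq <- sort(unique(c(reads, revcomp(reads))))
  k <- min_overlap_bp
  stopifnot(k >= 16L, all(nchar(uniq) >= k))
  pref <- substr(uniq, 1L, k)
  idx <- split(seq_along(uniq), pref)
  used <- logical(length(uniq))
  max_rl <- max(nchar(uniq))

  extend_right <- function(contig) {
    repeat {
      n <- nchar(contig)
      hit <- 0L; hit_L <- 0L
      for (L in seq(min(max_rl - 1L, n), k)) {
        key <- substr(contig, n - L + 1L, n - L + k)
        cand <- idx[[key]]
        if (is.null(cand)) next
        for (cc in cand) {
          if (used[cc]) next
          r <- uniq[cc]
          if (nchar(r) < L) next
          if (substr(r, 1L, L) != substr(contig, n - L + 1L, n)) next
          if (nchar(r) == L) { used[cc] <<- TRUE; next }
          if (L > hit_L) { hit <- cc; hit_L <- L }
        }
      }
      if (hit == 0L) return(contig)
      used[hit] <<- TRUE
      contig <- paste0(contig, substr(uniq[hit], hit_L + 1L, nchar(uniq[hit])))
    }
  }

  contigs <- character()
  for (i in seq_along(uniq)) {
    if (used[i]) next
    used[i] <- TRUE
    contig <- extend_right(uniq[i])
    contig <- revcomp(extend_right(revcomp(contig)))
    # consume reads contained in the finished contig (either strand is
    # present in uniq, so a fixed substring test suffices)
    rc <- revcomp(contig)
    for (j in which(!used)) {
      if (grepl(uniq[j], contig, fixed = TRUE) ||
          grepl(uniq[j], rc, fixed = TRUE)) {
        used[j] <- TRUE
      }
    }
    contigs <- c(contigs, contig)
  }
  canon <- pmin(contigs, revcomp(contigs))
  canon <- sort(unique(canon[nchar(canon) >= min_contig_len]))
  setNames(canon, sprintf("contig_%d", seq_along(canon)))
}

#' Cluster contigs by identity and coverage
#'
#' Greedy incremental clustering in the CD-HIT style: contigs are sorted by
#' length (descending, ties by id) and each joins the first existing cluster
#' whose representative aligns at `min_identity` identity over at least
#' `min_coverage_of_shorter` of the shorter sequence (both strands tried);
#' otherwise it founds a new cluster.
#'
#' @param contigs named character vector.
#' @param individuals named vector (contig id -> source individual id).
#' @param min_identity identity threshold (default 0.95).
#' @param min_coverage_of_shorter coverage threshold on the shorter sequence
#'   (default 0.70).
#' @return list of clusters: `representative`, `members`, `n_individuals`.
#' @export
cluster_contigs <- function(contigs, individuals,
                            min_identity = 0.95,
                            min_coverage_of_shorter = 0.70) {
  stopifnot(length(contigs) > 0L, !is.null(names(contigs)))
  ord <- order(-nchar(contigs), names(contigs))
  ids <- names(contigs)[ord]
  clusters <- list()
  for (id in ids) {
    seq_i <- contigs[[id]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_id <- clusters[[ci]]$representative
      rep_seq <- contigs[[rep_id]]
      st <- align_stats(seq_i, rep_seq)
      shorter <- min(nchar(seq_i), nchar(rep_seq))
      if (st$identity >= min_identity &&
          st$cols / shorter >= min_coverage_of_shorter) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(representative = id,
                                                members = id)
    }
  }
  lapply(clusters, function(cl) {
    cl$n_individuals <- length(unique(individuals[cl$members]))
    structure(cl, class = "contig_cluster")
  })
}

#' Consensus sequence of a contig cluster
#'
#' Star alignment against the representative: each member is locally aligned
#' to the representative and votes per representative column; the majority
#' base wins, ties break toward the representative. Insertions relative to
#' the representative are ignored.
#'
#' @param cluster `contig_cluster` from [cluster_contigs()].
#' @param contigs named character vector holding the member sequences.
#' @return consensus sequence (same length as the representative).
#' @export
consensus <- function(cluster, contigs) {
  rep_seq <- contigs[[cluster$representative]]
  others <- setdiff(cluster$members, cluster$representative)
  if (length(others) == 0L) return(rep_seq)
  n <- nchar(rep_seq)
  rep_bases <- strsplit(rep_seq, "")[[1]]
  votes <- matrix(0L, nrow = 5L, ncol = n,
                  dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  votes[cbind(match(rep_bases, rownames(votes)), seq_len(n))] <- 1L
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (id in others) {
    q <- contigs[[id]]
    st <- align_stats(q, rep_seq)
    if (st$flipped) q <- revcomp(q)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(rep_seq),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    qc <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sc <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    s_pos <- Biostrings::start(Biostrings::subject(al)) - 1L
    for (i in seq_along(qc)) {
      if (sc[i] != "-") s_pos <- s_pos + 1L
      if (sc[i] != "-" && qc[i] != "-") {
        r <- match(qc[i], rownames(votes))
        if (!is.na(r)) votes[r, s_pos] <- votes[r, s_pos] + 1L
      }
    }
  }
  # majority vote; ties resolve to the representative's base
  out <- rep_bases
  for (j in seq_len(n)) {
    mx <- max(votes[, j])
    if (votes[match(rep_bases[j], rownames(votes)), j] < mx) {
      out[j] <- rownames(votes)[which.max(votes[, j])]
    }
  }
  paste(out, collapse = "")
}

#' Filter consensus sequences against labelled databases
#'
#' A consensus is excluded when it aligns to any database sequence at
#' `min_identity` identity over at least `min_coverage` of the consensus
#' length; the label records the first matching database in the supplied
#' order (e.g. contaminants, genome patches, alternative assemblies).
#'
#' @param consensi named character vector.
#' @param filter_dbs named list of named character vectors (label -> FASTA
#'   contents); order fixes label precedence.
#' @param min_identity identity threshold (default 0.90).
#' @param min_coverage coverage-of-consensus threshold (default 0.50).
#' @return list with `retained` (named character vector) and `filtered`
#'   (data.frame `id`, `label`).
#' @export
filter_sequences <- function(consensi, filter_dbs,
                             min_identity = 0.90, min_coverage = 0.50) {
  filtered <- data.frame(id = character(), label = character(),
                         stringsAsFactors = FALSE)
  keep <- logical(length(consensi))
  names(keep) <- names(consensi)
  for (id in names(consensi)) {
    q <- consensi[[id]]
    label <- NA_character_
    for (db in names(filter_dbs)) {
      for (s in filter_dbs[[db]]) {
        st <- align_stats(q, s)
        if (st$identity >= min_identity &&
            st$cols / nchar(q) >= min_coverage) {
          label <- db
          break
        }
      }
      if (!is.na(label)) break
    }
    if (is.na(label)) keep[id] <- TRUE
    else filtered <- rbind(filtered, data.frame(id = id, label = label,
                                                stringsAsFactors = FALSE))
  }
  list(retained = consensi[keep], filtered = filtered)
}

#' Locate the reference-genome deletion site of a novel retrocopy
#'
#' The contig is located in an outgroup genome by local alignment. The outer
#' `min_anchor_bp` of the outgroup flank on each side is then anchored in
#' the reference genome by its unique exact match, and homology is extended
#' base by base from each anchor toward the retrocopy until reference and
#' outgroup first disagree. The deletion site is the reference interval
#' strictly between the two extension endpoints: a clean retrocopy deletion
#' gives a (near) zero-length site reported as a 1-bp insertion-point
#' interval, while a deletion that replaced the retrocopy region with other
#' sequence gives that residual interval. Ambiguous anchors (flank
#' duplicated in the reference) or inconsistent anchors (different
#' chromosomes, wrong order) yield a no-call with a reason code.
#'
#' @param contig retrocopy-bearing consensus sequence.
#' @param outgroup_genome named character vector of outgroup chromosomes.
#' @param reference_genome named character vector of reference chromosomes.
#' @param min_anchor_bp anchor seed length (default 40).
#' @param flank_bp outgroup flank length taken on each side (default 200).
#' @return list with `found`; on success `ref_interval`
#'   (`genomic_intervals`), `zero_length` flag, `outgroup_chrom`,
#'   `outgroup_interval`; on failure `reason`.
#' @export
locate_deletion_site <- function(contig, outgroup_genome, reference_genome,
                                 min_anchor_bp = 40L, flank_bp = 200L) {
  no <- function(reason) list(found = FALSE, reason = reason)
  best <- NULL
  for (chrom in names(outgroup_genome)) {
    st <- align_stats(contig, outgroup_genome[[chrom]])
    if (is.null(best) || st$score > best$st$score) {
      best <- list(chrom = chrom, st = st)
    }
  }
  if (is.null(best) || best$st$cols < 0.5 * nchar(contig)) {
    return(no("contig_not_in_outgroup"))
  }
  og <- outgroup_genome[[best$chrom]]
  os <- best$st$s_start; oe <- best$st$s_end
  if (os < flank_bp || oe + flank_bp > nchar(og)) return(no("flank_too_short"))
  left_seed_start <- os - flank_bp              # 0-based in outgroup
  right_seed_start <- oe + flank_bp - min_anchor_bp
  left_seed <- substr(og, left_seed_start + 1L,
                      left_seed_start + min_anchor_bp)
  right_seed <- substr(og, right_seed_start + 1L,
                       right_seed_start + min_anchor_bp)
  la <- unique_match(left_seed, reference_genome)
  ra <- unique_match(right_seed, reference_genome)
  if (is.character(la)) return(no(la))
  if (is.character(ra)) return(no(ra))
  if (la$chrom != ra$chrom) return(no("inconsistent_anchors"))
  ref <- reference_genome[[la$chrom]]
  # extend rightward from the left anchor while reference == outgroup
  left_end <- la$end
  op <- left_seed_start + min_anchor_bp
  while (left_end < nchar(ref) && op < nchar(og) &&
         substr(ref, left_end + 1L, left_end + 1L) ==
         substr(og, op + 1L, op + 1L)) {
    left_end <- left_end + 1L; op <- op + 1L
  }
  # extend leftward from the right anchor
  right_start <- ra$start
  op <- right_seed_start
  while (right_start > 0L && op > 0L &&
         substr(ref, right_start, right_start) == substr(og, op, op)) {
    right_start <- right_start - 1L; op <- op - 1L
  }
  if (ra$start < la$end) return(no("inconsistent_anchors"))
  zero_len <- right_start <= left_end
  ref_iv <- if (zero_len) gintervals(la$chrom, left_end, left_end + 1L)
            else gintervals(la$chrom, left_end, right_start)
  list(found = TRUE, ref_interval = ref_iv, zero_length = zero_len,
       outgroup_chrom = best$chrom,
       outgroup_interval = gintervals(best$chrom, os, oe))
}

# Unique exact match of a seed in the reference; "ambiguous_anchor" when the
# seed occurs more than once, "anchor_not_found" when absent.
# Returns list(chrom, start, end), 0-based half-open.
unique_match <- function(seed, reference_genome) {
  hits <- list()
  for (chrom in names(reference_genome)) {
    m <- Biostrings::matchPattern(seed,
                                  Biostrings::DNAString(reference_genome[[chrom]]))
    for (i in seq_len(length(m))) {
      hits[[length(hits) + 1L]] <- list(chrom = chrom,
                                        start = Biostrings::start(m)[i] - 1L,
                                        end = Biostrings::end(m)[i])
      if (length(hits) > 1L) return("ambiguous_anchor")
    }
  }
  if (length(hits) == 0L) return("anchor_not_found")
  hits[[1]]
}
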