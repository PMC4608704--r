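# Cache for the BLOSUM62 substitution matrix shipped with Biostrings.
.retrodup_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.retrodup_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .retrodup_env$BLOSUM62 <- e$BLOSUM62
  }
  .retrodup_env$BLOSUM62
}

#' Translated local alignment of a protein against genomic DNA
#'
#' Aligns the protein to all six conceptual translations of the DNA
#' (3 frames x 2 strands) with local (Smith-Waterman) scoring under BLOSUM62
#' and affine gaps, and returns the best-scoring frame. Because the single
#' optimal local alignment can bridge long low-similarity stretches (e.g. a
#' translated retained intron) between two strong anchors, the alignment is
#' post-split wherever its running score drops more than `xdrop` below its
#' running maximum — the X-drop rule used by seed-and-extend aligners — and
#' the best-scoring piece is reported. Identity is
#' `matches / gap-excluded aligned columns`; coverage is
#' `aligned parent residues / protein length`. Subject residues are mapped
#' back to 0-based half-open genomic codon intervals on the forward strand
#' of `dna`.
#'
#' @param protein amino-acid string (>= 20 residues).
#' @param dna DNA string (>= 60 bp).
#' @param gap_opening,gap_extension affine gap penalties (defaults 11 / 1).
#' @param xdrop score drop that terminates an alignment segment (default 25).
#' @return a `translated_alignment` object (list with `score`, `strand`,
#'   `frame`, `g_start`, `g_end`, `p_start`, `p_end`, `pairs`, `matches`,
#'   `cols`, `identity`, `coverage`), or `NULL` when no frame aligns with
#'   positive score.
#' @export
translated_align <- function(protein, dna, gap_opening = 11,
                             gap_extension = 1, xdrop = 25) {
  stopifnot(nchar(protein) >= 20L, nchar(dna) >= 60L)
  L <- nchar(dna)
  pat <- Biostrings::AAString(protein)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "-") revcomp(dna) else dna
    for (off in 0:2) {
      n <- ((L - off) %/% 3L) * 3L
      if (n < 3L) next
      aa <- translate_dna(substr(s, off + 1L, off + n))
      if (nchar(aa) < 1L) next
      al <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(aa), type = "local",
        substitutionMatrix = blosum62(),
        gapOpening = gap_opening, gapExtension = gap_extension)
      sc <- Biostrings::score(al)
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, strand = strand, frame = off, al = al)
      }
    }
  }
  if (is.null(best) || best$score <= 0) return(NULL)
  al <- best$al
  sm <- blosum62()
  pchars <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  schars <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  p_pos <- Biostrings::start(Biostrings::pattern(al)) - 1L
  s_pos <- Biostrings::start(Biostrings::subject(al)) - 1L
  nc <- length(pchars)
  col_p <- integer(nc); col_s <- integer(nc)
  col_match <- logical(nc); col_score <- numeric(nc)
  in_gap <- FALSE
  for (i in seq_len(nc)) {
    pg <- pchars[i] == "-"; sg <- schars[i] == "-"
    if (!pg) p_pos <- p_pos + 1L
    if (!sg) s_pos <- s_pos + 1L
    if (!pg && !sg) {
      col_p[i] <- p_pos; col_s[i] <- s_pos
      col_match[i] <- pchars[i] == schars[i]
      col_score[i] <- sm[pchars[i], schars[i]]
      in_gap <- FALSE
    } else {
      col_p[i] <- NA_integer_; col_s[i] <- NA_integer_
      col_score[i] <- -gap_extension - (!in_gap) * gap_opening
      in_gap <- TRUE
    }
  }
  seg <- best_xdrop_segment(col_score, xdrop)
  keep <- seg[1]:seg[2]
  aligned <- !is.na(col_p[keep])
  p_res <- col_p[keep][aligned]
  s_res <- col_s[keep][aligned]
  match <- col_match[keep][aligned]
  if (length(p_res) == 0L) return(NULL)
  off <- best$frame
  if (best$strand == "+") {
    g_start <- off + 3L * (s_res - 1L)
    g_end <- off + 3L * s_res
  } else {
    g_start <- L - off - 3L * s_res
    g_end <- L - off - 3L * (s_res - 1L)
  }
  pairs <- data.frame(p_res = p_res, g_start = g_start, g_end = g_end,
                      match = match)
  cols <- nrow(pairs)
  matches <- sum(match)
  structure(list(
    score = sum(col_score[keep]), strand = best$strand, frame = off,
    protein_len = nchar(protein), dna_len = L,
    p_start = min(p_res), p_end = max(p_res),
    g_start = min(g_start), g_end = max(g_end),
    pairs = pairs, matches = matches, cols = cols,
    identity = 100 * matches / cols,
    coverage = 100 * cols / nchar(protein)
  ), class = "translated_alignment")
}

# Split a column-score vector at X-drop points (running score falling more
# than `xdrop` below its running maximum ends a segment at that maximum),
# then return the best-scoring segment trimmed to its maximal-sum window
# (start, end indices) with weakly-anchored ends eroded.
best_xdrop_segment <- function(scores, xdrop) {
  n <- length(scores)
  best <- c(1L, n); best_score <- -Inf
  seg_start <- 1L
  run <- 0; run_max <- 0; run_max_at <- 0L
  close_segment <- function(s, e) {
    if (e < s) return()
    # maximal-sum subarray within the segment (Kadane with positions)
    cur <- 0; cur_start <- s; loc_best <- -Inf; b <- c(s, s)
    for (i in s:e) {
      if (cur <= 0) { cur <- 0; cur_start <- i }
      cur <- cur + scores[i]
      if (cur > loc_best) { loc_best <- cur; b <- c(cur_start, i) }
    }
    if (loc_best > best_score) { best_score <<- loc_best; best <<- b }
  }
  for (i in seq_len(n)) {
    run <- run + scores[i]
    if (run > run_max) { run_max <- run; run_max_at <- i }
    if (run_max - run > xdrop) {
      close_segment(seg_start, if (run_max_at >= seg_start) run_max_at else i)
      seg_start <- i + 1L
      run <- 0; run_max <- 0; run_max_at <- i
    }
  }
  close_segment(seg_start, n)
  # erode ends until they start with a solidly-scoring window, so that
  # chance-positive junk (e.g. translated intron) glued to a segment end by
  # the maximal-sum trim cannot masquerade as aligned flank
  W <- 10L; Tmin <- 12
  l <- best[1]; r <- best[2]
  while (r - l + 1L >= W && sum(scores[l:(l + W - 1L)]) < Tmin) l <- l + 1L
  while (r - l + 1L >= W && sum(scores[(r - W + 1L):r]) < Tmin) r <- r - 1L
  as.integer(c(l, r))
}

#' @export
print.translated_alignment <- function(x, ...) {
  cat(sprintf(
    "translated alignment: score %.1f, strand %s frame %d, residues %d-%d, genomic [%d,%d), identity %.1f%%, coverage %.1f%%\n",
    x$score, x$strand, x$frame, x$p_start, x$p_end, x$g_start, x$g_end,
    x$identity, x$coverage))
  invisible(x)
}
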