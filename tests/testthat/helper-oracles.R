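# Independent oracles kept deliberately separate from the package
# implementations they check.

# Affine-gap Smith-Waterman (Gotoh) on two residue strings; returns the best
# local score and the identity over gap-excluded aligned columns from a
# traceback. Small inputs only.
sw_protein_oracle <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)   # match state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (consume b)
  ptr <- array(0L, c(n + 1, m + 1))
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i, j], Y[i, j])
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  # traceback for identity (greedy through M; adequate for the check)
  matches <- 0; cols <- 0
  i <- bi; j <- bj
  while (i > 1 && j > 1 && M[i, j] > 0) {
    s <- submat[av[i - 1], bv[j - 1]]
    if (abs(M[i, j] - (M[i - 1, j - 1] + s)) < 1e-9 || M[i - 1, j - 1] + s >= max(X[i, j], Y[i, j])) {
      cols <- cols + 1
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (X[i, j] >= Y[i, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = best, identity = if (cols > 0) 100 * matches / cols else 0)
}

# Exhaustive two-sided Fisher p-value by direct enumeration with
# log-binomial coefficients (independent of dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  kk <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, kk) + lchoose(r2, c1 - kk) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[kk == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Per-base brute-force interval intersection length.
brute_overlap <- function(chrom1, s1, e1, chrom2, s2, e2) {
  if (chrom1 != chrom2) return(0L)
  sum((s1:(e1 - 1)) %in% (s2:(e2 - 1)))
}

# Random panel of populations x individuals.
make_panel <- function(pops, n_per_pop) {
  inds <- sprintf("I%04d", seq_len(length(pops) * n_per_pop))
  setNames(rep(pops, each = n_per_pop), inds)
}

blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Back-translate a protein with fixed (first listed) codons.
CODON_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- character()
  for (i in seq_along(gc)) {
    aa <- unname(gc[i])
    if (!aa %in% names(codons)) codons[aa] <- names(gc)[i]
  }
  codons
})

back_translate <- function(protein) {
  paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = "")
}

# Point mutation helper for building test fixtures (always changes the base).
mutate_dna_test <- function(dna, rate) {
  bases <- strsplit(dna, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  paste(bases, collapse = "")
}
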