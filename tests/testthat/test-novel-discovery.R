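test_that("error-free reads assemble into a near-identical contig", {
  set.seed(91)
  tpl <- c(t1 = random_dna(800))
  reads <- simulate_reads(tpl, 100, 20, error_rate = 0, seed = 92)
  contigs <- assemble_contigs(reads, 31, 500)
  expect_length(contigs, 1L)
  expect_gte(nchar(contigs[[1]]), 500L)
  # the contig is a substring of the template (up to strand), so identity
  # over its aligned length is 100% and >= 99% of the template is covered
  canon <- contigs[[1]]
  hit <- grepl(canon, tpl[[1]], fixed = TRUE) ||
    grepl(canon, revcomp(tpl[[1]]), fixed = TRUE)
  expect_true(hit)
  # uniform read placement leaves at most a few uncovered bases at the tips
  expect_gte(nchar(canon) / 800, 0.98)
})

test_that("assembly is strand-symmetric and drops short fragments", {
  set.seed(93)
  tpl <- c(t1 = random_dna(700))
  reads <- simulate_reads(tpl, 100, 20, error_rate = 0, seed = 94)
  a <- assemble_contigs(reads, 31, 500)
  b <- assemble_contigs(unname(revcomp(reads)), 31, 500)
  expect_identical(unname(a), unname(b))
  # two non-overlapping reads cannot reach the length cutoff
  expect_length(assemble_contigs(c(random_dna(100), random_dna(100)), 31, 500),
                0L)
})

test_that("clustering groups near-identical contigs and counts individuals", {
  set.seed(95)
  base <- random_dna(900)
  contigs <- c(c1 = base, c2 = base, c3 = random_dna(850))
  inds <- c(c1 = "ind1", c2 = "ind2", c3 = "ind1")
  cl <- cluster_contigs(contigs, inds)
  expect_length(cl, 2L)
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  expect_setequal(sizes, c(2L, 1L))
  big <- cl[[which(sizes == 2L)]]
  expect_equal(big$n_individuals, 2L)
  # a reverse-complement member still joins its cluster
  contigs2 <- c(c1 = base, c2 = revcomp(base))
  cl2 <- cluster_contigs(contigs2, c(c1 = "i1", c2 = "i2"))
  expect_length(cl2, 1L)
})

test_that("planted contig families are recovered exactly by clustering", {
  set.seed(96)
  n_fam <- 20
  contigs <- character(); inds <- character(); truth <- character()
  for (f in seq_len(n_fam)) {
    base <- random_dna(sample(600:1000, 1))
    for (m in 1:sample(1:3, 1)) {
      id <- sprintf("f%02d_m%d", f, m)
      contigs[id] <- mutate_dna_test(base, 0.02)   # intra-family >= 97%
      inds[id] <- sprintf("ind%d", m)
      truth[id] <- sprintf("f%02d", f)
    }
  }
  cl <- cluster_contigs(contigs, inds)
  expect_length(cl, n_fam)
  for (x in cl) {
    expect_length(unique(truth[x$members]), 1L)
  }
})

test_that("consensus takes the majority base and ties go to the representative", {
  set.seed(97)
  base <- random_dna(700)
  v1 <- base
  substr(v1, 100, 100) <- if (substr(base, 100, 100) == "A") "C" else "A"
  contigs <- c(a = base, b = base, c = v1)
  cl <- cluster_contigs(contigs, c(a = "i1", b = "i2", c = "i3"))
  expect_length(cl, 1L)
  cons <- consensus(cl[[1]], contigs)
  expect_identical(cons, base)
  # singleton: representative unchanged
  cl1 <- cluster_contigs(contigs["a"], c(a = "i1"))
  expect_identical(consensus(cl1[[1]], contigs["a"]), base)
})

test_that("consensus recovers the planted sequence from noisy members", {
  set.seed(98)
  base <- random_dna(800)
  contigs <- setNames(vapply(1:5, function(i) mutate_dna_test(base, 0.01),
                             character(1)), sprintf("m%d", 1:5))
  cl <- cluster_contigs(contigs, setNames(sprintf("i%d", 1:5), names(contigs)))
  expect_length(cl, 1L)
  cons <- consensus(cl[[1]], contigs)
  rep_len <- nchar(contigs[[cl[[1]]$representative]])
  matches <- sum(strsplit(cons, "")[[1]] == strsplit(base, "")[[1]])
  expect_gte(matches / rep_len, 0.995)
})

test_that("filtering excludes database hits with the first matching label", {
  set.seed(99)
  contaminant <- random_dna(900)
  patch <- random_dna(850)
  novel <- random_dna(800)
  dbs <- list(contaminant = c(v1 = contaminant), patch = c(p1 = patch))
  consensi <- c(x_cont = contaminant, x_patch = patch, x_novel = novel,
                x_cont_rc = revcomp(contaminant))
  out <- filter_sequences(consensi, dbs)
  expect_setequal(names(out$retained), "x_novel")
  expect_equal(out$filtered$label[out$filtered$id == "x_cont"], "contaminant")
  expect_equal(out$filtered$label[out$filtered$id == "x_cont_rc"], "contaminant")
  expect_equal(out$filtered$label[out$filtered$id == "x_patch"], "patch")
  # bookkeeping is conserved
  expect_equal(length(out$retained) + nrow(out$filtered), length(consensi))
})

test_that("deletion sites are located exactly in a synthetic trio", {
  set.seed(101)
  A <- random_dna(800); B <- random_dna(800); retro <- random_dna(300)
  x <- random_dna(20); y <- random_dna(25); z <- random_dna(110)
  outg <- c(chrA = paste0(A, x, retro, y, B))
  # residual 110 bp between the anchors (Table-3-style interval)
  ref1 <- c(chr1 = paste0(random_dna(300), A, z, B, random_dna(300)))
  s1 <- locate_deletion_site(retro, outg, ref1)
  expect_true(s1$found)
  expect_equal(c(s1$ref_interval$start, s1$ref_interval$end),
               c(1100L, 1210L))
  expect_false(s1$zero_length)
  # clean deletion: adjacent anchors reported as a 1-bp insertion point
  ref2 <- c(chr1 = paste0(random_dna(300), A, B, random_dna(300)))
  s2 <- locate_deletion_site(retro, outg, ref2)
  expect_true(s2$found)
  expect_true(s2$zero_length)
  expect_equal(s2$ref_interval$end - s2$ref_interval$start, 1L)
  # duplicated anchor seed -> ambiguous (the left seed sits 200 bp before
  # the contig, which starts at outgroup position 820)
  seed_left <- substr(outg[[1]], 820 - 200 + 1, 820 - 200 + 40)
  ref3 <- c(chr1 = paste0(ref2[[1]], random_dna(50), seed_left))
  s3 <- locate_deletion_site(retro, outg, ref3)
  expect_false(s3$found)
  expect_equal(s3$reason, "ambiguous_anchor")
  # contig absent from the outgroup
  s4 <- locate_deletion_site(random_dna(300), c(chrA = random_dna(2000)), ref1)
  expect_false(s4$found)
})

test_that("the discovery pipeline recovers planted novel retrocopies end to end", {
  set.seed(103)
  gsim <- simulate_genome_with_genes(2, c(4, 5), 16000, seed = 104,
                                     exon_bp_range = c(150L, 240L))
  templates <- character(); outg <- character(); ref <- character()
  planted <- list()
  for (i in 1:2) {
    m <- gsim$models[[i]]
    A <- random_dna(700); B <- random_dna(700)
    rp <- retropose(m, "ACGT", divergence = 0.08, seed = 105 + i,
                    insert_at = 2L)
    # unmapped reads only cover the novel (deleted-from-reference) region,
    # so the read template is the retrocopy itself; its genomic context
    # exists only in the outgroup
    templates[sprintf("novel%d", i)] <- rp$retro_seq
    outg[sprintf("chrO%d", i)] <- paste0(A, rp$retro_seq, B)
    ref[sprintf("chr%d", i)] <- paste0(random_dna(250), A, B, random_dna(250))
    planted[[i]] <- rp
  }
  contaminant <- c(v1 = random_dna(900))
  templates["decoy"] <- contaminant[[1]]
  contigs <- character(); individuals <- character()
  for (j in 1:2) {
    reads <- simulate_reads(templates, 100, 20, error_rate = 0,
                            seed = 110 + j)
    ct <- assemble_contigs(reads, 31, 500)
    names(ct) <- sprintf("ind%d_%s", j, names(ct))
    contigs <- c(contigs, ct)
    individuals <- c(individuals,
                     setNames(rep(sprintf("ind%d", j), length(ct)), names(ct)))
  }
  clusters <- cluster_contigs(contigs, individuals)
  consensi <- vapply(clusters, consensus, character(1), contigs = contigs)
  names(consensi) <- sprintf("cons%d", seq_along(consensi))
  filt <- filter_sequences(consensi, list(contaminant = contaminant))
  expect_equal(nrow(filt$filtered), 1L)
  expect_equal(filt$filtered$label, "contaminant")
  # every planted template is recovered among retained consensi at >= 99% id
  for (i in 1:2) {
    tpl <- templates[[sprintf("novel%d", i)]]
    hit <- FALSE
    for (cons in filt$retained) {
      st <- retrodup:::align_stats(cons, tpl)
      if (st$cols >= 0.95 * nchar(tpl) && st$identity >= 0.99) hit <- TRUE
    }
    expect_true(hit, info = sprintf("novel%d recovered", i))
  }
  # the retained consensi contain callable retrocopies with correct parents
  calls <- call_retrocopies(gsim$models, filt$retained)
  expect_gte(nrow(calls), 2L)
  expect_setequal(unique(calls$parent_gene), c("gene001", "gene002"))
  # and their deletion sites localize to the planted junction
  for (i in seq_len(nrow(calls))) {
    cons <- filt$retained[[calls$target[i]]]
    site <- locate_deletion_site(cons, outg, ref)
    expect_true(site$found)
    expect_true(site$zero_length)
  }
})

mutate_dna_test <- function(dna, rate) {
  bases <- strsplit(dna, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  paste(bases, collapse = "")
}
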