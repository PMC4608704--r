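test_that("translated alignment of a protein to its back-translation is perfect", {
  set.seed(51)
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                       replace = TRUE), collapse = "")
  dna <- back_translate(prot)
  al <- translated_align(prot, dna)
  expect_equal(al$identity, 100)
  expect_equal(al$coverage, 100)
  expect_equal(al$strand, "+")
  expect_equal(c(al$g_start, al$g_end), c(0L, nchar(dna)))
  # strand symmetry: reverse complement aligns identically on the minus strand
  al2 <- translated_align(prot, revcomp(dna))
  expect_equal(al2$identity, 100)
  expect_equal(al2$coverage, 100)
  expect_equal(al2$strand, "-")
  expect_equal(c(al2$g_start, al2$g_end), c(0L, nchar(dna)))
})

test_that("translated alignment identity agrees with a Smith-Waterman oracle", {
  # diverged retrocopies: compare against an independent DP over the
  # correct translated frame
  for (i in 1:10) {
    sim <- simulate_genome_with_genes(1, c(2, 3), 8000, seed = 500 + i)
    m <- sim$models[[1]]
    rp <- retropose(m, random_dna(400), divergence = 0.10, seed = 600 + i)
    al <- translated_align(m$protein, rp$target)
    frame_dna <- substr(rp$target, al$frame + 1,
                        al$frame + ((nchar(rp$target) - al$frame) %/% 3) * 3)
    frame_aa <- translate_dna(frame_dna)
    oracle <- sw_protein_oracle(m$protein, frame_aa, blosum62_test)
    expect_equal(al$score, oracle$score, tolerance = 1e-9)
    expect_lt(abs(al$identity - oracle$identity), 5)
  }
})

test_that("intron-loss inference is exact on synthetic retrocopies", {
  # full intronless copy of a multi-exon gene: all junctions collapsed
  sim <- simulate_genome_with_genes(1, c(5, 5), 12000, seed = 52)
  m <- sim$models[[1]]
  expect_equal(m$n_introns, 4L)
  rp <- retropose(m, random_dna(500), divergence = 0, seed = 53)
  al <- translated_align(m$protein, rp$target)
  expect_equal(infer_lost_introns(al, m), 4L)
  # single-exon parent: always 0
  s1 <- simulate_genome_with_genes(1, c(1, 1), 5000, seed = 54)
  rp1 <- retropose(s1$models[[1]], random_dna(500), divergence = 0, seed = 55)
  al1 <- translated_align(s1$models[[1]]$protein, rp1$target)
  expect_equal(infer_lost_introns(al1, s1$models[[1]]), 0L)
})

test_that("inferred intron loss equals generator truth across divergence and partial splicing", {
  checked <- 0L
  for (i in 1:40) {
    sim <- simulate_genome_with_genes(1, c(3, 5), 10000, seed = 700 + i)
    m <- sim$models[[1]]
    n_lost <- sample(seq(0L, m$n_introns), 1L)
    div <- runif(1, 0, 0.20)
    rp <- retropose(m, random_dna(1500), divergence = div,
                    n_introns_lost = n_lost, seed = 800 + i,
                    chrom_seq = sim$genome[["chr1"]])
    al <- translated_align(m$protein, rp$target)
    expect_equal(infer_lost_introns(al, m), rp$truth$introns_lost,
                 info = sprintf("case %d (div %.2f, lost %d)", i, div, n_lost))
    checked <- checked + 1L
  }
  expect_equal(checked, 40L)
})

test_that("intron-loss count never exceeds the parent's intron count", {
  for (i in 1:10) {
    sim <- simulate_genome_with_genes(1, c(2, 5), 10000, seed = 900 + i)
    m <- sim$models[[1]]
    rp <- retropose(m, random_dna(800), divergence = 0.05, seed = 950 + i)
    al <- translated_align(m$protein, rp$target)
    expect_lte(infer_lost_introns(al, m), m$n_introns)
  }
})

test_that("ORF conservation detects frameshifts and tolerates in-frame indels", {
  sim <- simulate_genome_with_genes(1, c(2, 3), 8000, seed = 56)
  cds <- sim$models[[1]]$mrna
  expect_true(conserved_orf(cds, cds))
  # 1-bp deletion mid-sequence: frameshift
  mut1 <- paste0(substr(cds, 1, 150), substr(cds, 152, nchar(cds)))
  expect_false(conserved_orf(mut1, cds))
  # 3-bp in-frame deletion with no created stop
  mut3 <- paste0(substr(cds, 1, 150), substr(cds, 154, nchar(cds)))
  expect_true(conserved_orf(mut3, cds))
})

test_that("ORF conservation matches a codon-walk construction oracle", {
  sim <- simulate_genome_with_genes(1, c(2, 2), 8000, seed = 57)
  cds <- sim$models[[1]]$mrna
  n <- nchar(cds)
  set.seed(58)
  for (i in 1:100) {
    kind <- sample(c("inframe_del", "frameshift_del", "stop", "clean"), 1)
    # cut positions on codon boundaries keep the construction's truth known
    codon_cut <- 3 * sample(10:(n %/% 3 - 10), 1)
    if (kind == "inframe_del") {
      mut <- paste0(substr(cds, 1, codon_cut), substr(cds, codon_cut + 4, n))
      expected <- TRUE
    } else if (kind == "frameshift_del") {
      k <- sample(c(1, 2, 4), 1)
      mut <- paste0(substr(cds, 1, codon_cut), substr(cds, codon_cut + k + 1, n))
      expected <- FALSE
    } else if (kind == "stop") {
      mut <- paste0(substr(cds, 1, codon_cut), "TAA",
                    substr(cds, codon_cut + 4, n))
      expected <- FALSE
    } else {
      mut <- cds
      expected <- TRUE
    }
    expect_identical(conserved_orf(mut, cds), expected,
                     info = sprintf("case %d: %s at %d", i, kind, codon_cut))
  }
})

test_that("classification applies each acceptance criterion strictly and in order", {
  fake_al <- function(span, identity, coverage) {
    structure(list(score = 100, strand = "+", frame = 0, protein_len = 100,
                   dna_len = 1000, p_start = 1, p_end = 100,
                   g_start = 0L, g_end = as.integer(span),
                   pairs = data.frame(p_res = integer(), g_start = integer(),
                                      g_end = integer(), match = logical()),
                   matches = identity, cols = 100,
                   identity = identity, coverage = coverage),
              class = "translated_alignment")
  }
  model <- list(gene_id = "g", transcript_id = "t", strand = "+",
                cds = gintervals("chr1", c(0, 200), c(100, 300), "+"))
  expect_equal(classify_retrocopy(NULL, model)$reason, "no_alignment")
  expect_equal(classify_retrocopy(fake_al(149, 90, 90), model)$reason,
               "min_span")
  # identity exactly 50% is rejected: the rule is strictly greater than
  expect_equal(classify_retrocopy(fake_al(500, 50, 90), model)$reason,
               "min_identity")
  expect_equal(classify_retrocopy(fake_al(500, 90, 50), model)$reason,
               "min_coverage")
  expect_equal(classify_retrocopy(fake_al(500, 90, 90), model)$reason,
               "min_introns_lost")
})

test_that("classification is monotone in the thresholds", {
  sim <- simulate_genome_with_genes(1, c(3, 4), 8000, seed = 59)
  m <- sim$models[[1]]
  rp <- retropose(m, random_dna(800), divergence = 0.1, seed = 60)
  al <- translated_align(m$protein, rp$target)
  base <- retrocopy_thresholds()
  expect_true(classify_retrocopy(al, m, base)$accepted)
  for (fld in c("min_span_bp", "min_identity_pct", "min_coverage_pct",
                "min_introns_lost")) {
    th <- base
    th[[fld]] <- th[[fld]] * 1000
    expect_false(classify_retrocopy(al, m, th)$accepted)
  }
})

test_that("the caller finds planted retrocopies at their loci with the right parent", {
  sim <- simulate_genome_with_genes(2, c(3, 4), 16000, seed = 61)
  target <- random_dna(8000)
  rp1 <- retropose(sim$models[[1]], target, divergence = 0.05, seed = 62,
                   insert_at = 1000L)
  rp2 <- retropose(sim$models[[2]], rp1$target, divergence = 0.05, seed = 63,
                   insert_at = 5000L)
  calls <- call_retrocopies(sim$models, c(contig1 = rp2$target))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$parent_gene, c("gene001", "gene002"))
  # boundaries within 15 bp of the planted loci
  len1 <- nchar(rp1$retro_seq)
  expect_lt(abs(calls$g_start[1] - 1000), 15)
  expect_lt(abs(calls$g_end[1] - (1000 + len1)), 15)
  # empty target set
  expect_equal(nrow(call_retrocopies(sim$models, character())), 0L)
})

test_that("overlapping calls on one locus reduce to the best-scoring parent", {
  sim <- simulate_genome_with_genes(1, c(3, 4), 8000, seed = 64)
  m <- sim$models[[1]]
  # a second, slightly diverged duplicate of the same gene model competes
  m2 <- m
  m2$gene_id <- "gene_dup"
  m2$transcript_id <- "tx_dup"
  m2$protein <- paste0(substr(m$protein, 1, nchar(m$protein) - 5), "AAAAA")
  rp <- retropose(m, random_dna(1000), divergence = 0, seed = 65)
  calls <- call_retrocopies(list(m, m2), c(t1 = rp$target))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$parent_gene, m$gene_id)
})
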