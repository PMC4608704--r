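test_that("genome simulation is seed-deterministic and structurally valid", {
  a <- simulate_genome_with_genes(5, c(2, 4), 40000, seed = 3)
  b <- simulate_genome_with_genes(5, c(2, 4), 40000, seed = 3)
  expect_identical(a, b)
  one <- simulate_genome_with_genes(1, c(1, 1), 5000, seed = 4)
  expect_equal(one$models[[1]]$n_introns, 0L)
  # CDS translates without internal stops
  for (m in a$models) {
    aa <- translate_dna(m$mrna)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  expect_error(simulate_genome_with_genes(50, c(4, 6), 5000, seed = 5),
               "too small")
})

test_that("generator exon/intron coordinates re-validate from the emitted GTF", {
  sim <- simulate_genome_with_genes(15, c(2, 5), 120000, seed = 6)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$models, gtf)
  models <- read_gene_models(gtf, genome = sim$genome)
  for (m in models) {
    pieces <- substring(sim$genome[[m$chrom]], m$exons$start + 1, m$exons$end)
    spliced <- paste(pieces, collapse = "")
    if (m$strand == "-") spliced <- revcomp(spliced)
    orig <- Filter(function(x) x$transcript_id == m$transcript_id, sim$models)[[1]]
    expect_identical(spliced, orig$mrna)
  }
})

test_that("retroposition with no divergence and all introns lost equals the mRNA", {
  sim <- simulate_genome_with_genes(1, c(3, 4), 10000, seed = 7)
  m <- sim$models[[1]]
  rp <- retropose(m, random_dna(2000), divergence = 0, truncate_frac = 0,
                  seed = 8)
  expect_identical(rp$retro_seq, m$mrna)
  expect_true(rp$truth$orf_intact)
  # the insertion locus carries the retrocopy
  expect_identical(substr(rp$target, rp$locus$start + 1, rp$locus$end),
                   rp$retro_seq)
})

test_that("losing one junction of a multi-exon gene retains the other introns", {
  sim <- simulate_genome_with_genes(1, c(3, 3), 10000, seed = 9)
  m <- sim$models[[1]]
  rp <- retropose(m, random_dna(2000), divergence = 0, n_introns_lost = 1,
                  seed = 10, chrom_seq = sim$genome[["chr1"]])
  # length = mRNA + retained intron(s)
  intron_total <- (max(m$exons$end) - min(m$exons$start)) - nchar(m$mrna)
  expect_gt(nchar(rp$retro_seq), nchar(m$mrna))
  expect_lt(nchar(rp$retro_seq), nchar(m$mrna) + intron_total)
  # the spliced (3'-most) junction is present as a contiguous exon-exon join
  parts <- retrodup:::gene_oriented_parts(m, sim$genome[["chr1"]])
  junction <- paste0(substr(parts$exons[2], nchar(parts$exons[2]) - 19, nchar(parts$exons[2])),
                     substr(parts$exons[3], 1, 20))
  expect_true(grepl(junction, rp$retro_seq, fixed = TRUE))
  # the retained (5'-most) intron is still there
  expect_true(grepl(parts$introns[1], rp$retro_seq, fixed = TRUE))
})

test_that("observed retrocopy divergence is binomially consistent with the rate", {
  sim <- simulate_genome_with_genes(1, c(2, 3), 10000, seed = 11)
  m <- sim$models[[1]]
  L <- nchar(m$mrna)
  div <- 0.1
  within <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    rp <- retropose(m, random_dna(500), divergence = div, seed = 100 + i)
    mm <- sum(strsplit(rp$retro_seq, "")[[1]] != strsplit(m$mrna, "")[[1]])
    # substitution resampling can silently keep a base; observed rate is
    # binomial around div with a small downward bias bound
    sd3 <- 3 * sqrt(div * (1 - div) / L)
    if (abs(mm / L - div) <= sd3) within <- within + 1
  }
  expect_gte(within / n_sim, 0.95)
})

test_that("population genotypes honor degenerate planted frequencies", {
  panel <- make_panel(c("CEU", "YRI"), 5)
  del <- gintervals("chr1", c(0, 1000), c(300, 1400), id = c("d0", "d1"))
  f0 <- matrix(0, 2, 2, dimnames = list(del$id, c("CEU", "YRI")))
  sim0 <- simulate_population_genotypes(del, panel, f0, seed = 12)
  expect_true(all(vapply(sim0$deletions, function(d) all(d$genotypes == 0L),
                         logical(1))))
  f1 <- matrix(1, 2, 2, dimnames = list(del$id, c("CEU", "YRI")))
  sim1 <- simulate_population_genotypes(del, panel, f1, seed = 13)
  expect_true(all(vapply(sim1$deletions, function(d) all(d$genotypes == 1L),
                         logical(1))))
  expect_error(simulate_population_genotypes(
    del, panel, matrix(0.5, 2, 2, dimnames = list(del$id, c("CEU", "XXX"))),
    seed = 1), "unknown population|cover every")
})

test_that("ortholog presence sets follow the tree under the loss model", {
  tree <- eutherian_tree()
  sim0 <- simulate_ortholog_blocks(tree, loss_prob = 0, n_retrocopies = 60,
                                   seed = 14)
  # no losses: survivors are all descendants of the origin, and when the
  # origin is internal the identifiable origin equals the planted rollup
  for (i in seq_len(nrow(sim0$truth))) {
    tr <- sim0$truth[i, ]
    survivors <- strsplit(tr$survivors, ",")[[1]]
    if (length(survivors) >= 2) {
      expect_identical(tr$identifiable_origin, tr$origin_node)
    } else {
      # terminal-branch origin: single-species presence set
      expect_length(survivors, 1L)
    }
  }
  # determinism
  sim0b <- simulate_ortholog_blocks(tree, loss_prob = 0, n_retrocopies = 60,
                                    seed = 14)
  expect_identical(sim0, sim0b)
})

test_that("NB counts match their planted moments and fold changes", {
  groups <- setNames(rep(c("A", "B"), each = 10), sprintf("s%02d", 1:20))
  # Poisson fallback: variance/mean ratio near 1
  simp <- simulate_counts_nb(2000, groups, size_factors = setNames(rep(1, 20), names(groups)),
                             dispersion = 0, de_fraction = 0, baseline = 500,
                             seed = 15)
  ratio <- mean(apply(simp$counts, 1, var) / rowMeans(simp$counts))
  expect_lt(abs(ratio - 1), 0.1)
  expect_true(all(simp$truth$log2fc == 0))
  # planted log2fc = 2 gives a group-mean ratio near 4
  simfc <- simulate_counts_nb(400, groups, size_factors = setNames(rep(1, 20), names(groups)),
                              dispersion = 0.1, de_fraction = 0.5,
                              log2fc = 2, baseline = 500, seed = 16)
  de <- simfc$truth$log2fc != 0
  up <- simfc$truth$log2fc > 0
  ratios <- rowMeans(simfc$counts[, 11:20]) / rowMeans(simfc$counts[, 1:10])
  # per-locus sampling noise at n=10, dispersion 0.1 leaves ~15% relative SD
  # on the ratio: the planted 4x change must hold in aggregate and for the
  # bulk of loci
  expect_lt(abs(mean(ratios[up]) - 4) / 4, 0.1)
  expect_lt(abs(mean(ratios[de & !up]) - 0.25) / 0.25, 0.1)
  expect_gt(mean(abs(ratios[up] - 4) / 4 < 0.25), 0.85)
})

test_that("simulated reads tile templates at the requested coverage", {
  tpl <- c(t1 = random_dna(1000))
  reads <- simulate_reads(tpl, 100, 20, error_rate = 0, seed = 17)
  expect_equal(length(reads), 200L)
  expect_true(all(nchar(reads) == 100L))
  rc <- revcomp(tpl[[1]])
  ok <- vapply(reads, function(r) {
    grepl(r, tpl[[1]], fixed = TRUE) || grepl(r, rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  # error process: realized mismatch fraction within 3 SDs of the rate
  reads_e <- simulate_reads(tpl, 100, 10, error_rate = 0.02, seed = 18)
  nm <- 0; tot <- 0
  for (nm_i in seq_along(reads_e)) {
    info <- strsplit(names(reads_e)[nm_i], "_")[[1]]
    start <- as.integer(info[3]); strand <- info[4]
    truth <- substr(tpl[[1]], start + 1, start + 100)
    if (strand == "-") truth <- revcomp(truth)
    nm <- nm + sum(strsplit(reads_e[[nm_i]], "")[[1]] != strsplit(truth, "")[[1]])
    tot <- tot + 100
  }
  # substitution resampling: observed rate binomial around error_rate
  expect_lt(abs(nm / tot - 0.02), 3 * sqrt(0.02 * 0.98 / tot))
})

test_that("qPCR truth obeys the doubling arithmetic and curves are monotone", {
  s <- simulate_qpcr_curves(c(1e-6, 5e-7), efficiency = 2, noise = 0,
                            seed = 19)
  expect_equal(s$truth$true_ct[2] - s$truth$true_ct[1], 1)
  expect_true(all(diff(s$curves$well1) >= 0))
  expect_true(all(diff(s$curves$well2) >= 0))
})
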