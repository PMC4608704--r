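#' Default pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its default value
#' (retrocopy acceptance 150 bp / 50% / 50% / 2 introns; RDV overlap 100 bp;
#' ortholog reciprocal overlap 50%; contig length 500 bp; clustering
#' 95%/70%; expression 1 RPM; DE mean-count filter 50, fold change 2,
#' adjusted p 0.05; Ct cut-off 32; efficiency bound 1.8) plus the sizes used
#' by the synthetic-data stage.
#'
#' @param workdir directory for stage inputs/outputs (created if needed).
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
pipeline_config <- function(workdir, seed = 1L) {
  list(
    workdir = workdir,
    seed = as.integer(seed),
    thresholds = list(
      min_span_bp = 150L, min_identity_pct = 50, min_coverage_pct = 50,
      min_introns_lost = 2L, min_overlap_bp = 100L,
      min_reciprocal_overlap = 0.5, min_overlap_asm_bp = 31L,
      min_contig_len = 500L, cluster_identity = 0.95,
      cluster_coverage = 0.70, filter_identity = 0.90, filter_coverage = 0.50,
      min_anchor_bp = 40L, rpm_threshold = 1, min_mean_reads = 50,
      min_fold_change = 2, max_adjusted_p = 0.05, ct_cutoff = 32,
      min_efficiency = 1.8),
    simulate = list(
      n_genes = 6L, genome_length = 50000L, target_length = 30000L,
      n_planted_retro = 4L, divergence = 0.08,
      populations = c("ASW", "CEU", "CHB", "CHS", "CLM", "FIN", "GBR",
                      "IBS", "JPT", "LWK", "MXL", "PUR", "TSI", "YRI"),
      inds_per_pop = 10L, n_deletions = 10L,
      n_ortholog_retrocopies = 40L, ortholog_loss_prob = 0.15,
      n_count_loci = 400L, samples_per_group = 8L, de_fraction = 0.05,
      de_log2fc = 2, dispersion = 0.1, count_baseline = c(100, 1000),
      n_novel = 2L, novel_individuals = 2L, read_length = 100L,
      coverage = 20, n_qpcr_wells = 6L)
  )
}

stage_order <- c("simulate", "annotate", "rdv", "conserve", "discover",
                 "express", "stats")

#' Run the RDV analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> annotate -> rdv -> conserve -> discover -> express ->
#' stats) over the configured working directory and writes a JSON manifest
#' recording parameters, input hashes and outputs. Reruns with the same
#' configuration and seed are identical for all deterministic stages.
#'
#' @param config list from [pipeline_config()].
#' @param stages character vector of stage names (default: all).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, stages = stage_order) {
  bad <- setdiff(stages, stage_order)
  if (length(bad) > 0L) stopf("unknown stage: %s", bad[1])
  stages <- stage_order[stage_order %in% stages]
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, thresholds = config$thresholds,
                   stages = list())
  for (st in stages) {
    fn <- switch(st, simulate = stage_simulate, annotate = stage_annotate,
                 rdv = stage_rdv, conserve = stage_conserve,
                 discover = stage_discover, express = stage_express,
                 stats = stage_stats)
    check_stage_inputs(st, config)
    outputs <- fn(config)
    manifest$stages[[st]] <- list(
      outputs = outputs,
      md5 = as.list(tools::md5sum(file.path(config$workdir, outputs))))
    names(manifest$stages[[st]]$md5) <- outputs
  }
  jsonlite::write_json(manifest,
                       file.path(config$workdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_inputs <- list(
  simulate = character(),
  annotate = c("genome.fa", "genes.gtf"),
  rdv = c("retrocopies.bed", "deletions.vcf", "panel.tsv"),
  conserve = c("blocks.maf", "species_loci.tsv", "tree.nwk"),
  discover = c("filter_db_contaminant.fa", "filter_db_patch.fa",
               "outgroup.fa", "reference.fa", "genes.gtf", "genome.fa"),
  express = c("counts.tsv", "sample_groups.tsv"),
  stats = c("ct_table.tsv", "qpcr_curves.tsv")
)

check_stage_inputs <- function(stage, config) {
  need <- stage_inputs[[stage]]
  have <- file.exists(file.path(config$workdir, need))
  if (!all(have)) {
    stopf("stage %s: missing input %s", stage, need[!have][1])
  }
}

wpath <- function(config, ...) file.path(config$workdir, ...)

stage_simulate <- function(config) {
  sc <- config$simulate
  th <- config$thresholds
  seed <- config$seed
  out <- character()

  # genome, genes, planted retrocopies on a separate target chromosome
  gsim <- simulate_genome_with_genes(sc$n_genes,
                                     genome_length = sc$genome_length,
                                     seed = child_seed(seed, 1))
  set.seed(child_seed(seed, 2))
  target <- random_dna(sc$target_length)
  planted <- list()
  pos <- 2000L
  for (i in seq_len(sc$n_planted_retro)) {
    m <- gsim$models[[(i - 1L) %% length(gsim$models) + 1L]]
    rp <- retropose(m, target, divergence = sc$divergence,
                    seed = child_seed(seed, 10 + i), insert_at = pos)
    target <- rp$target
    planted[[i]] <- rp$truth
    pos <- pos + nchar(rp$retro_seq) + 4000L
  }
  # long-mRNA parents for the novel-discovery templates live on their own
  # chromosome so every novel retrocopy clears the 500 bp contig cutoff
  nsim <- simulate_genome_with_genes(sc$n_novel, c(4L, 5L),
                                     genome_length = sc$n_novel * 3000L + 2000L,
                                     seed = child_seed(seed, 19),
                                     exon_bp_range = c(150L, 240L))
  for (k in seq_along(nsim$models)) {
    nsim$models[[k]]$chrom <- "chr_n"
    nsim$models[[k]]$exons$chrom <- "chr_n"
    nsim$models[[k]]$cds$chrom <- "chr_n"
    nsim$models[[k]]$gene_id <- sprintf("ngene%03d", k)
    nsim$models[[k]]$transcript_id <- sprintf("ntx%03d", k)
  }
  names(nsim$proteins) <- sprintf("ntx%03d", seq_along(nsim$proteins))
  all_models <- c(gsim$models, nsim$models)
  genome <- c(gsim$genome, chr_n = unname(nsim$genome["chr1"]),
              chr_t = target)
  write_fasta(genome, wpath(config, "genome.fa")); out <- c(out, "genome.fa")
  write_gtf(all_models, wpath(config, "genes.gtf")); out <- c(out, "genes.gtf")
  write_fasta(c(gsim$proteins, nsim$proteins), wpath(config, "proteins.fa"))
  out <- c(out, "proteins.fa")
  retro_loci <- do.call(rbind, lapply(planted, function(tr) {
    iv <- tr$locus; iv$chrom <- "chr_t"; iv$id <- paste0(iv$id, "_", iv$start)
    iv
  }))
  write_bed(retro_loci, wpath(config, "retrocopies.bed"))
  out <- c(out, "retrocopies.bed")

  # panel + deletion genotypes at planted frequencies
  pops <- sc$populations
  inds <- sprintf("I%04d", seq_len(length(pops) * sc$inds_per_pop))
  panel <- setNames(rep(pops, each = sc$inds_per_pop), inds)
  write_panel(panel, wpath(config, "panel.tsv")); out <- c(out, "panel.tsv")
  set.seed(child_seed(seed, 3))
  n_del <- sc$n_deletions
  del_ids <- sprintf("DEL%03d", seq_len(n_del))
  # half the deletions overlap planted retrocopies, half fall elsewhere
  del_rows <- list()
  for (i in seq_len(n_del)) {
    if (i <= nrow(retro_loci)) {
      s <- retro_loci$start[i] - sample(0:50, 1L)
      e <- retro_loci$start[i] + pmax(100L, interval_length(retro_loci)[i] %/% 2L)
    } else {
      s <- sample.int(sc$target_length - 500L, 1L)
      e <- s + sample(120:400, 1L)
    }
    del_rows[[i]] <- gintervals("chr_t", max(0L, s), e, id = del_ids[i])
  }
  del_loci <- do.call(rbind, del_rows)
  freqs <- matrix(round(runif(n_del * length(pops))^3, 3),
                  nrow = n_del, dimnames = list(del_ids, pops))
  freqs[runif(length(freqs)) < 0.5] <- 0
  gsimp <- simulate_population_genotypes(del_loci, panel, freqs,
                                         seed = child_seed(seed, 4))
  write_sv_vcf(gsimp$deletions, wpath(config, "deletions.vcf"))
  out <- c(out, "deletions.vcf")
  write.table(data.frame(deletion = rownames(freqs), freqs,
                         check.names = FALSE),
              wpath(config, "truth_frequencies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- c(out, "truth_frequencies.tsv")

  # ortholog blocks on the eutherian tree
  tree <- eutherian_tree()
  ape::write.tree(tree, wpath(config, "tree.nwk")); out <- c(out, "tree.nwk")
  osim <- simulate_ortholog_blocks(tree, sc$ortholog_loss_prob,
                                   sc$n_ortholog_retrocopies,
                                   seed = child_seed(seed, 5),
                                   min_reciprocal_overlap = th$min_reciprocal_overlap)
  write_maf_blocks(osim$blocks, wpath(config, "blocks.maf"))
  out <- c(out, "blocks.maf")
  write.table(osim$loci, wpath(config, "species_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- c(out, "species_loci.tsv")
  write.table(osim$truth, wpath(config, "truth_orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- c(out, "truth_orthologs.tsv")

  # count matrix for two populations
  groups <- setNames(rep(c("GBR", "YRI"), each = sc$samples_per_group),
                     sprintf("S%02d", seq_len(2L * sc$samples_per_group)))
  csim <- simulate_counts_nb(sc$n_count_loci, groups,
                             dispersion = sc$dispersion,
                             de_fraction = sc$de_fraction,
                             log2fc = sc$de_log2fc,
                             baseline = sc$count_baseline,
                             seed = child_seed(seed, 6))
  write_counts(csim$counts, wpath(config, "counts.tsv"))
  out <- c(out, "counts.tsv")
  write.table(data.frame(names(groups), unname(groups)),
              wpath(config, "sample_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  out <- c(out, "sample_groups.tsv")
  write.table(csim$truth, wpath(config, "truth_de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- c(out, "truth_de.tsv")

  # novel-retrocopy discovery inputs: templates, reads, filter dbs, trio
  set.seed(child_seed(seed, 7))
  templates <- character(); outg <- character(); ref <- character()
  for (i in seq_len(sc$n_novel)) {
    m <- nsim$models[[i]]
    A <- random_dna(800); B <- random_dna(800)
    rp <- retropose(m, "ACGT", divergence = sc$divergence,
                    seed = child_seed(seed, 20 + i), insert_at = 2L)
    # unmapped reads cover only the novel region: the read template is the
    # retrocopy itself, whose genomic context exists only in the outgroup
    templates[sprintf("novel%d", i)] <- rp$retro_seq
    outg[sprintf("chrO%d", i)] <- paste0(A, rp$retro_seq, B)
    ref[sprintf("chr%d", i)] <- paste0(random_dna(350), A, B, random_dna(350))
  }
  contaminant <- c(viral1 = random_dna(900))
  patch <- c(patch1 = random_dna(850))
  templates <- c(templates, decoy_contaminant = contaminant[[1]],
                 decoy_patch = patch[[1]])
  write_fasta(contaminant, wpath(config, "filter_db_contaminant.fa"))
  write_fasta(patch, wpath(config, "filter_db_patch.fa"))
  write_fasta(outg, wpath(config, "outgroup.fa"))
  write_fasta(ref, wpath(config, "reference.fa"))
  out <- c(out, "filter_db_contaminant.fa", "filter_db_patch.fa",
           "outgroup.fa", "reference.fa")
  for (j in seq_len(sc$novel_individuals)) {
    reads <- simulate_reads(templates, sc$read_length, sc$coverage,
                            error_rate = 0, seed = child_seed(seed, 30 + j))
    write_fasta(reads, wpath(config, sprintf("reads_ind%d.fa", j)))
    out <- c(out, sprintf("reads_ind%d.fa", j))
  }

  # qPCR curves and Ct table
  set.seed(child_seed(seed, 8))
  q0 <- 10^runif(sc$n_qpcr_wells, -7, -4)
  eff <- runif(sc$n_qpcr_wells, 1.75, 2.0)
  qsim <- simulate_qpcr_curves(q0, eff, n_cycles = 40L, noise = 0.001,
                               seed = child_seed(seed, 9))
  curve_df <- do.call(rbind, lapply(names(qsim$curves), function(w) {
    data.frame(well = w, cycle = seq_along(qsim$curves[[w]]),
               fluorescence = qsim$curves[[w]])
  }))
  write.table(curve_df, wpath(config, "qpcr_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(qsim$truth, wpath(config, "truth_qpcr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ct <- data.frame(sample = qsim$truth$well, target = "retrogene",
                   ct_target = round(qsim$truth$true_ct, 2),
                   ct_reference = 20)
  write.table(ct, wpath(config, "ct_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- c(out, "qpcr_curves.tsv", "truth_qpcr.tsv", "ct_table.tsv")
  message(sprintf("simulate: %d genes, %d planted retrocopies, %d deletions, %d ortholog retrocopies",
                  sc$n_genes, sc$n_planted_retro, sc$n_deletions,
                  sc$n_ortholog_retrocopies))
  out
}

stage_annotate <- function(config) {
  th <- config$thresholds
  genome <- read_fasta(wpath(config, "genome.fa"))
  models <- read_gene_models(wpath(config, "genes.gtf"), genome = genome)
  cds <- setNames(
    vapply(models, function(m) {
      spliced_sequence(genome[[m$chrom]], m$cds, m$strand)
    }, character(1)),
    vapply(models, `[[`, character(1), "transcript_id"))
  targets <- genome[setdiff(names(genome), unique(vapply(models, `[[`,
                                                         character(1), "chrom")))]
  thresholds <- retrocopy_thresholds(th$min_span_bp, th$min_identity_pct,
                                     th$min_coverage_pct, th$min_introns_lost)
  calls <- call_retrocopies(models, targets, thresholds, parent_cds = cds)
  write.table(calls, wpath(config, "retrocopy_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(calls) > 0L) {
    write_bed(gintervals(calls$target, calls$g_start, calls$g_end,
                         calls$strand, calls$retrocopy_id),
              wpath(config, "retrocopy_calls.bed"))
  } else {
    writeLines(character(), wpath(config, "retrocopy_calls.bed"))
  }
  message(sprintf("annotate: %d retrocopy calls on %d target sequences",
                  nrow(calls), length(targets)))
  c("retrocopy_calls.tsv", "retrocopy_calls.bed")
}

stage_rdv <- function(config) {
  th <- config$thresholds
  retro <- read_bed(wpath(config, "retrocopies.bed"))
  panel <- read_panel(wpath(config, "panel.tsv"))
  dels <- read_sv_vcf(wpath(config, "deletions.vcf"), panel)
  tab <- build_rdv_table(retro, dels, panel, th$min_overlap_bp)
  write_rdv_table(tab, wpath(config, "rdv_table.tsv"))
  jsonlite::write_json(as.list(summarize_spread(tab)),
                       wpath(config, "spread_summary.json"),
                       auto_unbox = TRUE)
  message(sprintf("rdv: %d records from %d retrocopies x %d deletions",
                  nrow(tab), nrow(retro), length(dels)))
  c("rdv_table.tsv", "spread_summary.json")
}

stage_conserve <- function(config) {
  th <- config$thresholds
  blocks <- read_maf_blocks(wpath(config, "blocks.maf"))
  loci <- read.table(wpath(config, "species_loci.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
  tree <- ape::read.tree(wpath(config, "tree.nwk"))
  groups <- map_orthologs(blocks, loci, th$min_reciprocal_overlap)
  tab <- write_ortholog_table(groups, tree,
                              wpath(config, "ortholog_groups.tsv"))
  counts <- summarize_lineage_counts(groups, tree)
  jsonlite::write_json(counts, wpath(config, "lineage_counts.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  message(sprintf("conserve: %d groups (%d with assigned origin)",
                  length(groups), sum(!is.na(tab$origin_clade))))
  c("ortholog_groups.tsv", "lineage_counts.json")
}

stage_discover <- function(config) {
  th <- config$thresholds
  read_files <- sort(list.files(config$workdir, "^reads_.*\\.fa$"))
  contigs <- character(); individuals <- character()
  for (f in read_files) {
    ind <- sub("^reads_(.*)\\.fa$", "\\1", f)
    ct <- assemble_contigs(read_fasta(wpath(config, f)),
                           th$min_overlap_asm_bp, th$min_contig_len)
    names(ct) <- paste0(ind, "_", names(ct))
    contigs <- c(contigs, ct)
    individuals <- c(individuals, setNames(rep(ind, length(ct)), names(ct)))
  }
  clusters <- cluster_contigs(contigs, individuals, th$cluster_identity,
                              th$cluster_coverage)
  consensi <- vapply(clusters, consensus, character(1), contigs = contigs)
  names(consensi) <- sprintf("consensus_%d", seq_along(consensi))
  dbs <- list(contaminant = read_fasta(wpath(config, "filter_db_contaminant.fa")),
              patch = read_fasta(wpath(config, "filter_db_patch.fa")))
  filt <- filter_sequences(consensi, dbs, th$filter_identity,
                           th$filter_coverage)
  genome <- read_fasta(wpath(config, "genome.fa"))
  models <- read_gene_models(wpath(config, "genes.gtf"), genome = genome)
  thresholds <- retrocopy_thresholds(th$min_span_bp, th$min_identity_pct,
                                     th$min_coverage_pct, th$min_introns_lost)
  calls <- call_retrocopies(models, filt$retained, thresholds)
  outg <- read_fasta(wpath(config, "outgroup.fa"))
  ref <- read_fasta(wpath(config, "reference.fa"))
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cons <- filt$retained[[calls$target[i]]]
    site <- locate_deletion_site(cons, outg, ref, th$min_anchor_bp)
    cl <- clusters[[as.integer(sub("consensus_", "", calls$target[i]))]]
    rows[[i]] <- data.frame(
      retrocopy = sprintf("rdn%d", i),
      length_bp = calls$genomic_span_bp[i],
      parental_gene = calls$parent_gene[i],
      deletion_site = if (site$found) {
        sprintf("%s:%d-%d", site$ref_interval$chrom,
                site$ref_interval$start, site$ref_interval$end)
      } else sprintf("none(%s)", site$reason),
      identity_protein_pct = round(calls$identity_pct[i], 2),
      n_individuals = cl$n_individuals,
      stringsAsFactors = FALSE)
  }
  novel <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(retrocopy = character(), length_bp = integer(),
               parental_gene = character(), deletion_site = character(),
               identity_protein_pct = numeric(), n_individuals = integer())
  write_fasta(contigs, wpath(config, "contigs.fa"))
  write_fasta(filt$retained, wpath(config, "retained_consensi.fa"))
  cluster_tab <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    data.frame(cluster = sprintf("consensus_%d", i),
               representative = clusters[[i]]$representative,
               n_members = length(clusters[[i]]$members),
               n_individuals = clusters[[i]]$n_individuals,
               members = paste(clusters[[i]]$members, collapse = ","))
  }))
  write.table(cluster_tab, wpath(config, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(filt$filtered, wpath(config, "filtered_sequences.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(novel, wpath(config, "novel_retrocopies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf(
    "discover: %d contigs -> %d clusters -> %d retained (%d filtered: %s) -> %d novel retrocopies",
    length(contigs), length(clusters), length(filt$retained),
    nrow(filt$filtered),
    paste(sprintf("%s=%d", names(table(filt$filtered$label)),
                  table(filt$filtered$label)), collapse = ", "),
    nrow(novel)))
  c("contigs.fa", "clusters.tsv", "retained_consensi.fa",
    "filtered_sequences.tsv", "novel_retrocopies.tsv")
}

stage_express <- function(config) {
  th <- config$thresholds
  counts <- read_counts(wpath(config, "counts.tsv"))
  groups <- read_sample_groups(wpath(config, "sample_groups.tsv"))
  rpm <- rpm_normalize(counts)
  expressed <- flag_expressed(rpm, th$rpm_threshold)
  write.table(data.frame(locus = names(expressed),
                         max_rpm = apply(rpm, 1L, max),
                         expressed = expressed),
              wpath(config, "expressed_flags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res <- nb_differential_test(counts, groups, th$min_mean_reads)
  sig <- call_differential(res, th$min_fold_change, th$max_adjusted_p)
  write.table(res, wpath(config, "de_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sig, wpath(config, "de_significant.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("express: %d/%d loci expressed; %d tested, %d significant",
                  sum(expressed), length(expressed),
                  sum(is.na(res$skipped)), nrow(sig)))
  c("expressed_flags.tsv", "de_results.tsv", "de_significant.tsv")
}

stage_stats <- function(config) {
  th <- config$thresholds
  ct <- read_ct_table(wpath(config, "ct_table.tsv"))
  ct <- quantify_ct_table(ct, th$ct_cutoff)
  write.table(ct, wpath(config, "qpcr_quantities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  curves <- read_fluorescence(wpath(config, "qpcr_curves.tsv"))
  eff <- do.call(rbind, lapply(names(curves), function(w) {
    e <- estimate_efficiency(curves[[w]])
    data.frame(well = w, efficiency = e$efficiency,
               r_squared = e$r_squared, acceptable = e$acceptable)
  }))
  write.table(eff, wpath(config, "qpcr_efficiency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # association between expression flag and differential-expression call
  fisher <- NULL
  if (file.exists(wpath(config, "expressed_flags.tsv")) &&
      file.exists(wpath(config, "de_results.tsv"))) {
    fl <- read.table(wpath(config, "expressed_flags.tsv"), sep = "\t",
                     header = TRUE)
    de <- read.table(wpath(config, "de_results.tsv"), sep = "\t",
                     header = TRUE)
    de$sig <- !is.na(de$padj) & de$padj < th$max_adjusted_p &
      abs(de$log2fc) >= log2(th$min_fold_change)
    merged <- merge(fl, de[, c("locus", "sig")], by = "locus", all.x = TRUE)
    merged$sig[is.na(merged$sig)] <- FALSE
    tab <- matrix(c(sum(merged$expressed & merged$sig),
                    sum(merged$expressed & !merged$sig),
                    sum(!merged$expressed & merged$sig),
                    sum(!merged$expressed & !merged$sig)), 2L, 2L,
                  byrow = TRUE)
    fisher <- list(table = as.list(as.vector(tab)),
                   p_value = fisher_exact_2x2(tab))
  }
  jsonlite::write_json(
    list(n_expressed_quantified = sum(ct$expressed),
         mean_efficiency = mean(eff$efficiency),
         all_efficiencies_acceptable = all(eff$acceptable),
         fisher_expression_vs_de = fisher),
    wpath(config, "stats_summary.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("stats: %d/%d targets expressed; mean efficiency %.3f",
                  sum(ct$expressed), nrow(ct), mean(eff$efficiency)))
  c("qpcr_quantities.tsv", "qpcr_efficiency.tsv", "stats_summary.json")
}
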