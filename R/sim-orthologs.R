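#' Default eutherian species tree
#'
#' Fourteen species with the internal clades used for origin-lineage
#' assignment named (Hominidae, Catarrhini, Primates, Murinae, Glires,
#' Euarchontoglires, Laurasiatheria, Boreoeutheria, Eutheria). Unnamed
#' internal nodes (e.g. the human-chimpanzee ancestor) roll up to the
#' smallest enclosing named clade.
#'
#' @return an `ape::phylo` tree with node labels.
#' @export
eutherian_tree <- function() {
  nwk <- paste0(
    "((((((((human,chimpanzee),gorilla),orangutan)Hominidae,",
    "macaque)Catarrhini,marmoset)Primates,",
    "((mouse,rat)Murinae,rabbit)Glires)Euarchontoglires,",
    "((dog,cat),(cow,horse))Laurasiatheria)Boreoeutheria,elephant)Eutheria;"
  )
  ape::read.tree(text = nwk)
}

# Name of the smallest named clade containing node `node` (itself included);
# leaves roll up to their nearest named ancestor.
named_rollup <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  labels <- c(rep(NA_character_, n_tip), tree$node.label)
  labels[labels == ""] <- NA_character_
  cur <- node
  repeat {
    if (!is.na(labels[cur])) return(labels[cur])
    parent <- tree$edge[tree$edge[, 2] == cur, 1]
    if (length(parent) == 0L) return(NA_character_)
    cur <- parent
  }
}

# Leaf labels descending from a node (the node itself if it is a leaf).
descendant_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_leaves, tree = tree))
}

#' Simulate ortholog presence and alignment blocks on a species tree
#'
#' Each retrocopy is planted at a random node of the tree; every branch
#' below the origin loses the retrocopy independently with probability
#' `loss_prob`, and the presence set is the surviving leaves. For each
#' retrocopy with survivors, one (ungapped) alignment block is emitted with
#' a row per surviving species, plus per-species retrocopy loci jittered
#' within the block so that true orthologs keep a reciprocal overlap above
#' `min_reciprocal_overlap`. Optional decoy loci overlap the block by much
#' less than the threshold and must come out as singletons.
#'
#' @param tree `ape::phylo` with named clades (default [eutherian_tree()]).
#' @param loss_prob per-branch loss probability.
#' @param n_retrocopies number of retrocopies to simulate.
#' @param seed RNG seed.
#' @param len_range retrocopy length range (bp).
#' @param jitter_frac maximum locus shift as a fraction of length.
#' @param decoy_prob probability of adding a sub-threshold decoy locus.
#' @param min_reciprocal_overlap threshold the jitter must respect.
#' @return list with `blocks` (MAF-style block data.frames), `loci`
#'   (data.frame species/chrom/start/end/id), and `truth` (data.frame with
#'   planted origin node, identifiable origin = named rollup of the
#'   survivors' MRCA, survivor list, and member locus ids).
#' @export
simulate_ortholog_blocks <- function(tree = eutherian_tree(),
                                     loss_prob = 0.1,
                                     n_retrocopies = 100L,
                                     seed = 1L,
                                     len_range = c(300L, 900L),
                                     jitter_frac = 0.15,
                                     decoy_prob = 0.2,
                                     min_reciprocal_overlap = 0.5) {
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  blocks <- list()
  loci <- data.frame(species = character(), chrom = character(),
                     start = integer(), end = integer(), id = character(),
                     stringsAsFactors = FALSE)
  truth <- data.frame(retrocopy = character(), origin_node = character(),
                      identifiable_origin = character(),
                      survivors = character(), members = character(),
                      stringsAsFactors = FALSE)
  for (r in seq_len(n_retrocopies)) {
    rid <- sprintf("rc%04d", r)
    origin <- sample.int(n_node, 1L)
    survivors <- simulate_survivors(tree, origin, loss_prob)
    ident <- NA_character_
    if (length(survivors) >= 2L) {
      mrca <- ape::getMRCA(tree, survivors)
      ident <- named_rollup(tree, mrca)
    }
    members <- character()
    if (length(survivors) > 0L) {
      L <- sample(seq(len_range[1], len_range[2]), 1L)
      base <- random_dna(L)
      block <- data.frame(species = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), src_size = integer(),
                          text = character(), stringsAsFactors = FALSE)
      for (sp in survivors) {
        # disjoint per-retrocopy placement window, so loci of different
        # retrocopies never collide on a species genome
        bstart <- (r - 1L) * 3000L + sample.int(500L, 1L)
        block <- rbind(block, data.frame(
          species = sp, chrom = "chr1", start = bstart, end = bstart + L,
          strand = "+", src_size = 2000000L, text = base,
          stringsAsFactors = FALSE))
        shift <- sample(seq(-floor(jitter_frac * L), floor(jitter_frac * L)), 1L)
        llen <- round(L * runif(1, 0.9, 1.1))
        ls <- max(bstart, bstart + shift)
        le <- min(bstart + L, ls + llen)
        lid <- sprintf("%s_%s", rid, sp)
        loci <- rbind(loci, data.frame(
          species = sp, chrom = "chr1", start = ls, end = le, id = lid,
          stringsAsFactors = FALSE))
        members <- c(members, lid)
        # at most one decoy per block: decoys must stay sub-threshold
        # against every projected locus, including other decoys
        if (sp == survivors[1] && runif(1) < decoy_prob) {
          ds <- bstart + floor(0.85 * L)
          loci <- rbind(loci, data.frame(
            species = sp, chrom = "chr1", start = ds, end = ds + L,
            id = sprintf("decoy_%s_%s", rid, sp), stringsAsFactors = FALSE))
        }
      }
      blocks[[length(blocks) + 1L]] <- block
    }
    origin_name <- named_rollup(tree, origin)
    truth <- rbind(truth, data.frame(
      retrocopy = rid, origin_node = origin_name,
      identifiable_origin = ident,
      survivors = paste(survivors, collapse = ","),
      members = paste(members, collapse = ","),
      stringsAsFactors = FALSE))
  }
  list(blocks = blocks, loci = loci, truth = truth)
}

# Leaves below `origin` still carrying the retrocopy after independent
# per-branch losses.
simulate_survivors <- function(tree, origin, loss_prob) {
  n_tip <- length(tree$tip.label)
  if (origin <= n_tip) return(tree$tip.label[origin])
  walk <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- character()
    for (k in kids) {
      if (runif(1) < loss_prob) next
      if (k <= n_tip) out <- c(out, tree$tip.label[k])
      else out <- c(out, walk(k))
    }
    out
  }
  walk(origin)
}
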