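# Project a forward-strand genomic interval onto alignment-block columns.
# Returns a 0-based half-open column interval, or NULL when the interval
# does not intersect the row.
project_to_block <- function(row, start, end) {
  a <- max(start, row$start); b <- min(end, row$end)
  if (b <= a) return(NULL)
  if (row$strand == "+") {
    ra <- a - row$start; rb <- b - row$start
  } else {
    ra <- row$end - b; rb <- row$end - a
  }
  chars <- strsplit(row$text, "")[[1]]
  cols <- which(chars != "-")
  c(cols[ra + 1L] - 1L, cols[rb])
}

#' Group retrocopies across species into ortholog groups
#'
#' Two retrocopies from different species are orthologous when, projected
#' through a shared alignment block onto block columns, each covers at least
#' `min_reciprocal_overlap` of the other's projected extent. Groups are the
#' connected components of this relation; loci absent from every block
#' become singleton groups.
#'
#' @param blocks list of block data.frames from [read_maf_blocks()].
#' @param loci data.frame with `species`, `chrom`, `start`, `end`, `id`.
#' @param min_reciprocal_overlap reciprocal-overlap threshold (default 0.5).
#' @return list of `ortholog_group` objects: `retrocopy_id` (human member if
#'   present), `members`, `presence` (species set), `species_loci`.
#' @export
map_orthologs <- function(blocks, loci, min_reciprocal_overlap = 0.5) {
  edges <- character(0)
  for (b in blocks) {
    proj <- list()
    for (i in seq_len(nrow(b))) {
      row <- b[i, , drop = FALSE]
      cand <- loci[loci$species == row$species & loci$chrom == row$chrom &
                     loci$start < row$end & loci$end > row$start, ,
                   drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        pc <- project_to_block(row, cand$start[j], cand$end[j])
        if (!is.null(pc)) {
          proj[[length(proj) + 1L]] <- list(id = cand$id[j],
                                            species = row$species,
                                            c1 = pc[1], c2 = pc[2])
        }
      }
    }
    if (length(proj) < 2L) next
    for (i in seq_len(length(proj) - 1L)) {
      for (j in seq(i + 1L, length(proj))) {
        pi <- proj[[i]]; pj <- proj[[j]]
        if (pi$species == pj$species) next
        ov <- min(pi$c2, pj$c2) - max(pi$c1, pj$c1)
        if (ov <= 0) next
        if (ov / (pi$c2 - pi$c1) >= min_reciprocal_overlap &&
            ov / (pj$c2 - pj$c1) >= min_reciprocal_overlap) {
          edges <- c(edges, pi$id, pj$id)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(loci$id))
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  groups <- list()
  for (k in sort(unique(comp))) {
    ids <- sort(names(comp)[comp == k])
    sub <- loci[loci$id %in% ids, , drop = FALSE]
    presence <- sort(unique(sub$species))
    human_ids <- sub$id[sub$species == "human"]
    groups[[length(groups) + 1L]] <- structure(
      list(retrocopy_id = if (length(human_ids) > 0L) human_ids[1] else ids[1],
           members = ids, presence = presence, species_loci = sub),
      class = "ortholog_group")
  }
  groups
}

#' Assign the origin lineage of an ortholog group
#'
#' A retrocopy is assigned to a lineage only when observed in at least two
#' species; the origin is the smallest named clade containing the MRCA of
#' the presence set. Single-species groups are unassignable under the
#' two-species rule and return `NA`.
#'
#' @param group `ortholog_group`.
#' @param tree `ape::phylo` with named clades.
#' @return clade name, or `NA_character_`.
#' @export
assign_origin_lineage <- function(group, tree) {
  sp <- group$presence
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp) > 0L) stopf("species not in tree: %s", missing_sp[1])
  if (length(sp) < 2L) return(NA_character_)
  named_rollup(tree, ape::getMRCA(tree, sp))
}

#' Is a human retrocopy ancestral?
#'
#' A human retrocopy is ancestral when it has an ortholog in at least one
#' other primate species (by default chimpanzee, gorilla, orangutan,
#' macaque or marmoset).
#'
#' @param group `ortholog_group` containing human.
#' @param primate_species other-primate species set.
#' @return logical.
#' @export
is_ancestral <- function(group,
                         primate_species = c("chimpanzee", "gorilla",
                                             "orangutan", "macaque",
                                             "marmoset")) {
  stopifnot("human" %in% group$presence)
  length(intersect(setdiff(group$presence, "human"), primate_species)) > 0L
}

#' Is a group conserved beyond Euarchontoglires?
#'
#' Flags very ancient retrocopies: presence in at least one species outside
#' the given clade.
#'
#' @param group `ortholog_group`.
#' @param tree `ape::phylo`.
#' @param clade clade name (default `Euarchontoglires`).
#' @return logical.
#' @export
is_deep_conserved <- function(group, tree, clade = "Euarchontoglires") {
  inside <- clade_species(tree, clade)
  length(setdiff(group$presence, inside)) > 0L
}

# Leaf species of a named clade.
clade_species <- function(tree, clade) {
  n_tip <- length(tree$tip.label)
  idx <- which(tree$node.label == clade)
  if (length(idx) != 1L) stopf("clade %s not found in tree", clade)
  descendant_leaves(tree, n_tip + idx)
}

#' Tally retroposition origins per lineage
#'
#' For each named clade, counts groups whose origin is that clade, and the
#' subset of those groups whose presence set includes human (retrocopies
#' detectable in the human genome).
#'
#' @param groups list of `ortholog_group`.
#' @param tree `ape::phylo` with named clades.
#' @return data.frame with `clade`, `n_origin`, `n_with_human`.
#' @export
summarize_lineage_counts <- function(groups, tree) {
  clades <- tree$node.label[tree$node.label != ""]
  origins <- vapply(groups, assign_origin_lineage, character(1), tree = tree)
  has_human <- vapply(groups, function(g) "human" %in% g$presence, logical(1))
  data.frame(
    clade = clades,
    n_origin = vapply(clades, function(cl) sum(origins == cl, na.rm = TRUE),
                      integer(1)),
    n_with_human = vapply(clades, function(cl) {
      sum(origins == cl & has_human, na.rm = TRUE)
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write ortholog groups as a TSV
#'
#' @param groups list of `ortholog_group`.
#' @param tree `ape::phylo` used for origin assignment and the deep flag.
#' @param path output path.
#' @return the table, invisibly.
#' @export
write_ortholog_table <- function(groups, tree, path) {
  rows <- lapply(groups, function(g) {
    data.frame(
      retrocopy_id = g$retrocopy_id,
      presence = paste(g$presence, collapse = ","),
      origin_clade = assign_origin_lineage(g, tree),
      ancestral = if ("human" %in% g$presence) is_ancestral(g) else NA,
      deep_conserved = is_deep_conserved(g, tree),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$retrocopy_id), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
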