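#' Read a population panel file
#'
#' Two-column TSV (individual id, population code), with or without a
#' header line named `individual`/`population`.
#'
#' @param path TSV path.
#' @return named character vector: individual id -> population code.
#' @export
read_panel <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "individual")) df <- df[-1, , drop = FALSE]
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stopf("individual %s appears twice in panel", ids[duplicated(ids)][1])
  }
  pops <- setNames(as.character(df[[2]]), ids)
  if (length(pops) == 0L) stopf("panel is empty")
  pops
}

#' Write a population panel file
#'
#' @param panel named character vector (individual -> population).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(data.frame(names(panel), unname(panel)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read deletion structural variants from a VCF
#'
#' Keeps records that are deletions: `SVTYPE=DEL` in INFO, or `REF` longer
#' than `ALT`. The deleted interval is converted to the internal 0-based
#' half-open convention: with a 1-bp anchor base, a record at `POS` with an
#' `L`-bp REF deletes `[POS, POS + L - 1)`; an `END` INFO tag (1-based
#' inclusive) takes precedence, giving `[POS, END)`. Phased (`|`) and
#' unphased (`/`) genotype separators are treated identically; malformed
#' genotypes become missing with a warning.
#'
#' @param path plain-text VCF 4.x with GT fields.
#' @param panel named vector from [read_panel()]; every sample in the VCF
#'   must be present in the panel.
#' @return list of `deletion_variant` objects, each a list with `id`,
#'   `locus` (`genomic_intervals` row) and `genotypes` (n x 2 integer
#'   matrix, NA = missing, rownames = individual ids).
#' @export
read_sv_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1]
  missing_panel <- setdiff(samples, names(panel))
  if (length(missing_panel) > 0L) {
    stopf("VCF individual %s absent from panel", missing_panel[1])
  }
  info <- fix[, "INFO"]
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alt <- fix[i, "ALT"]
    svtype <- sub(".*SVTYPE=([^;]+).*", "\\1", info[i])
    is_del <- (grepl("SVTYPE=", info[i]) && svtype == "DEL") ||
      (!is.na(ref) && !is.na(alt) && nchar(ref) > nchar(alt))
    if (!is_del) next
    pos <- as.integer(fix[i, "POS"])
    endm <- regmatches(info[i], regexpr("(^|;)END=[0-9]+", info[i]))
    if (length(endm) == 1L && nzchar(endm)) {
      del_end <- as.integer(sub(".*END=", "", endm))
      locus <- gintervals(fix[i, "CHROM"], pos, del_end)
    } else {
      locus <- gintervals(fix[i, "CHROM"], pos, pos + nchar(ref) - 1L)
    }
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") id <- sprintf("del_%d", i)
    gmat <- matrix(NA_integer_, nrow = length(samples), ncol = 2L,
                   dimnames = list(samples, c("a1", "a2")))
    raw <- sub(":.*$", "", gt[i, -1])
    parts <- strsplit(raw, "[/|]")
    for (j in seq_along(samples)) {
      al <- suppressWarnings(as.integer(parts[[j]]))
      if (length(al) == 2L && !anyNA(al) && all(al %in% 0:1)) {
        gmat[j, ] <- al
      } else if (!identical(parts[[j]], c(".", "."))) {
        warnf("malformed GT '%s' for %s at %s; set to missing",
              gt[i, j + 1L], samples[j], id)
      }
    }
    out[[i]] <- structure(
      list(id = id, locus = locus, genotypes = gmat),
      class = "deletion_variant"
    )
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write deletion variants as a VCF
#'
#' Inverse of [read_sv_vcf()]: emits `SVTYPE=DEL` records with symbolic
#' `<DEL>` ALT alleles and 1-based `POS`/`END` converted back from the
#' internal 0-based half-open loci.
#'
#' @param deletions list of `deletion_variant` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(deletions, path) {
  samples <- if (length(deletions) > 0L) rownames(deletions[[1]]$genotypes) else character()
  header <- c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(deletions, function(d) {
    gt <- apply(d$genotypes, 1L, function(a) {
      if (anyNA(a)) "./." else paste(a, collapse = "/")
    })
    paste(c(d$locus$chrom, d$locus$start, d$id, "N", "<DEL>", ".", "PASS",
            sprintf("SVTYPE=DEL;END=%d", d$locus$end), "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
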