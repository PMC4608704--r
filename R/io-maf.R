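#' Read MAF alignment blocks
#'
#' Parses a multiple-alignment (MAF) file into blocks. Each `s` row carries
#' strand-relative `start`/`size` fields; these are converted to
#' forward-strand 0-based half-open intervals: a `+` row spans
#' `[start, start + size)`, a `-` row with source size `N` spans
#' `[N - start - size, N - start)`.
#'
#' @param path MAF file.
#' @return list of blocks; each block is a data.frame with columns
#'   `species`, `chrom`, `start`, `end` (forward 0-based half-open),
#'   `strand`, `src_size`, `text` (gapped row).
#' @export
read_maf_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur) > 0L) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      cur <- data.frame(species = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), src_size = integer(),
                        text = character(), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0) substr(src, dot + 1L, nchar(src)) else src
      start_rel <- as.integer(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.integer(f[6]); text <- f[7]
      ngap <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ngap != size) {
        stopf("MAF row for %s: size %d inconsistent with %d aligned bases",
              src, size, ngap)
      }
      if (strand == "+") {
        fwd <- c(start_rel, start_rel + size)
      } else {
        fwd <- c(src_size - start_rel - size, src_size - start_rel)
      }
      cur <- rbind(cur, data.frame(
        species = species, chrom = chrom, start = fwd[1], end = fwd[2],
        strand = strand, src_size = src_size, text = text,
        stringsAsFactors = FALSE))
    } else if (!nzchar(trimws(ln)) || startsWith(ln, "#")) {
      flush()
    }
  }
  flush()
  blocks
}

#' Write MAF alignment blocks
#'
#' Inverse of [read_maf_blocks()]; forward-strand intervals are converted
#' back to strand-relative start/size fields.
#'
#' @param blocks list of block data.frames (see [read_maf_blocks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf_blocks <- function(blocks, path) {
  out <- c("##maf version=1")
  for (b in blocks) {
    out <- c(out, "a score=0")
    for (i in seq_len(nrow(b))) {
      size <- b$end[i] - b$start[i]
      start_rel <- if (b$strand[i] == "+") b$start[i] else b$src_size[i] - b$end[i]
      out <- c(out, sprintf("s %s.%s %d %d %s %d %s",
                            b$species[i], b$chrom[i], start_rel, size,
                            b$strand[i], b$src_size[i], b$text[i]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
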