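# Plain-text SAM parsing and CIGAR arithmetic.
#
# Only the fields the downstream analyses need are kept. Unmapped (0x4) and
# secondary (0x100) records are dropped; duplicates are intentionally kept.

#' Read a text SAM file into a read table
#'
#' @param path Path to a SAM file (text, coordinate-sorted).
#' @param check_sorted Error when alignments are not coordinate-sorted.
#' @return Tibble with one row per kept alignment: `qname`, `flag`, `chrom`,
#'   `pos` (0-based leftmost aligned position), `mapq`, `cigar`, `seq`,
#'   `qual` (`NA` when absent) and `strand`.
#' @export
read_sam <- function(path, check_sorted = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(qname = character(), flag = integer(), chrom = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character(), qual = character(), strand = character()))
  }
  fields <- stringr::str_split_fixed(lines, "\t", 12)
  bad <- which(!nzchar(fields[, 11]))
  if (length(bad) > 0) {
    abort(sprintf("malformed SAM record at alignment line %d", bad[1]))
  }
  reads <- tibble(
    qname = fields[, 1],
    flag = as.integer(fields[, 2]),
    chrom = fields[, 3],
    pos = as.integer(fields[, 4]) - 1L,
    mapq = as.integer(fields[, 5]),
    cigar = fields[, 6],
    seq = fields[, 10],
    qual = ifelse(fields[, 11] == "*", NA_character_, fields[, 11])
  ) |>
    filter(bitwAnd(.data$flag, 4L) == 0L, bitwAnd(.data$flag, 256L) == 0L) |>
    mutate(strand = ifelse(bitwAnd(.data$flag, 16L) > 0L, "-", "+"))
  if (check_sorted && !sam_is_sorted(reads)) {
    abort(sprintf("SAM file '%s' is not coordinate-sorted", path))
  }
  validate_cigar_lengths(reads)
  reads
}

sam_is_sorted <- function(reads) {
  if (nrow(reads) < 2) return(TRUE)
  chrom_blocks <- rle(reads$chrom)$values
  if (anyDuplicated(chrom_blocks) > 0) return(FALSE)
  all(unlist(tapply(reads$pos, factor(reads$chrom, levels = unique(reads$chrom)),
                    function(p) diff(p) >= 0)))
}

validate_cigar_lengths <- function(reads) {
  if (nrow(reads) == 0) return(invisible(TRUE))
  qlen <- purrr::map2_int(reads$cigar, reads$seq, function(cg, sq) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  })
  bad <- which(qlen != nchar(reads$seq))
  if (length(bad) > 0) {
    abort(sprintf("CIGAR/sequence length mismatch for read '%s'",
                  reads$qname[bad[1]]))
  }
  invisible(TRUE)
}

# CIGAR string -> list(op = character, len = integer)
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  list(op = m[, 3], len = as.integer(m[, 2]))
}

# Reference intervals (0-based half-open) covered by the aligned portion of a
# read. `ops` selects which CIGAR operations consume/cover reference bases.
aligned_intervals <- function(pos, cigar, ops = c("M", "=", "X", "D")) {
  cg <- parse_cigar(cigar)
  rpos <- pos
  starts <- integer(0); ends <- integer(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X", "D", "N")) {
      if (op %in% ops) {
        starts <- c(starts, rpos); ends <- c(ends, rpos + len)
      }
      rpos <- rpos + len
    }
  }
  if (length(starts) == 0) return(tibble(start = integer(), end = integer()))
  # merge adjacent intervals (e.g. M runs split by I)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  keep_s <- starts[1]; out_s <- integer(0); out_e <- integer(0); cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e) cur_e <- max(cur_e, ends[k])
    else { out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
           keep_s <- starts[k]; cur_e <- ends[k] }
  }
  tibble(start = c(out_s, keep_s), end = c(out_e, cur_e))
}

#' Read a reference FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are the first word of
#'   each FASTA header).
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a reference FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
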