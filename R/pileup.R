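# Pileup: per-position allele/strand/quality tallies from aligned reads.
#
# A pileup is a long tibble with one row per (position, allele):
#   chrom, pos (0-based), ref, allele, plus, minus, quals_plus, quals_minus
# Base alleles are A/C/G/T/N; insertions are "+SEQ" anchored at the aligned
# base they follow; deletions are "-L" at the first deleted base. Deleted
# positions carry no base evidence. quals_* are integer Phred lists aligned
# with the strand counts (empty when the input had no quality strings).

#' Build a pileup from SAM alignments
#'
#' @param sam Path to a coordinate-sorted text SAM file, or a read tibble as
#'   returned by [read_sam()].
#' @param reference Path to the reference FASTA, or a named character vector
#'   of chromosome sequences. Required to assign the reference base.
#' @param min_mapq Minimum mapping quality; reads below it are excluded
#'   (default 10).
#' @return A pileup tibble (see details above), ordered by chromosome
#'   appearance and position.
#' @export
pileup_from_sam <- function(sam, reference, min_mapq = 10) {
  reads <- if (is.character(sam)) read_sam(sam) else sam
  refs <- if (is.character(reference) && length(reference) == 1 &&
              file.exists(reference)) read_reference(reference) else reference
  reads <- filter(reads, .data$mapq >= min_mapq)
  missing_chrom <- setdiff(unique(reads$chrom), names(refs))
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome(s) absent from reference FASTA: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  pileup_reads(reads, refs)
}

pileup_reads <- function(reads, refs) {
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  allele = character(), plus = integer(), minus = integer(),
                  quals_plus = list(), quals_minus = list())
  if (nrow(reads) == 0) return(structure(empty, class = c("seqmine_pileup", class(empty))))
  events <- purrr::map(seq_len(nrow(reads)), function(i) {
    read_events(reads$pos[i], reads$cigar[i], reads$seq[i], reads$qual[i],
                reads$strand[i], reads$chrom[i])
  }) |> bind_rows()
  pu <- events |>
    group_by(.data$chrom, .data$pos, .data$allele) |>
    summarise(
      plus = sum(.data$strand == "+"),
      minus = sum(.data$strand == "-"),
      quals_plus = list(.data$qual[.data$strand == "+" & !is.na(.data$qual)]),
      quals_minus = list(.data$qual[.data$strand == "-" & !is.na(.data$qual)]),
      .groups = "drop") |>
    mutate(ref = substr(refs[.data$chrom], .data$pos + 1L, .data$pos + 1L)) |>
    select("chrom", "pos", "ref", "allele", "plus", "minus",
           "quals_plus", "quals_minus") |>
    mutate(chrom = factor(.data$chrom, levels = unique(reads$chrom))) |>
    arrange(.data$chrom, .data$pos, allele_rank(.data$allele), .data$allele) |>
    mutate(chrom = as.character(.data$chrom))
  structure(pu, class = c("seqmine_pileup", class(empty)))
}

# Per-read evidence: one row per aligned base / insertion / deletion event.
read_events <- function(pos, cigar, seq, qual, strand, chrom) {
  cg <- parse_cigar(cigar)
  q <- phred_to_int(qual)
  rpos <- pos; qpos <- 0L
  out <- vector("list", length(cg$op))
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      bases <- strsplit(substr(seq, qpos + 1L, qpos + len), "")[[1]]
      out[[k]] <- tibble(chrom = chrom, pos = rpos + seq_len(len) - 1L,
                         allele = bases,
                         qual = if (is.null(q)) NA_integer_ else q[qpos + seq_len(len)],
                         strand = strand)
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      if (rpos - 1L >= 0L) {
        out[[k]] <- tibble(chrom = chrom, pos = rpos - 1L,
                           allele = paste0("+", substr(seq, qpos + 1L, qpos + len)),
                           qual = NA_integer_, strand = strand)
      }
      qpos <- qpos + len
    } else if (op == "D") {
      out[[k]] <- tibble(chrom = chrom, pos = rpos,
                         allele = paste0("-", len),
                         qual = NA_integer_, strand = strand)
      rpos <- rpos + len
    } else if (op == "N") {
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    } # H, P consume nothing tracked here
  }
  bind_rows(out)
}

#' Total read depth per pileup position
#'
#' Depth counts base evidence only (A/C/G/T/N rows); insertion and deletion
#' rows are tallied separately in the pileup.
#'
#' @param pileup A pileup tibble.
#' @return Tibble with `chrom`, `pos`, `depth`.
#' @export
pileup_depth <- function(pileup) {
  pileup |>
    filter(is_base_allele(.data$allele)) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(depth = sum(.data$plus + .data$minus), .groups = "drop")
}

#' Write / read a pileup as TSV
#'
#' Positions are written 1-based for display; quality lists are comma-joined.
#' `read_pileup()` restores the exact in-memory representation.
#'
#' @param pileup A pileup tibble.
#' @param path File path.
#' @return `write_pileup()` the path, invisibly; `read_pileup()` a pileup tibble.
#' @export
write_pileup <- function(pileup, path) {
  out <- pileup |>
    mutate(pos = .data$pos + 1L,
           quals_plus = purrr::map_chr(.data$quals_plus, join_quals),
           quals_minus = purrr::map_chr(.data$quals_minus, join_quals))
  readr::write_tsv(out, path)
  invisible(path)
}

join_quals <- function(q) if (length(q) == 0) "." else paste(q, collapse = ",")

split_quals <- function(s) {
  if (is.na(s) || s == ".") integer(0) else as.integer(strsplit(s, ",")[[1]])
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  pu <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", allele = "c",
    plus = "i", minus = "i", quals_plus = "c", quals_minus = "c")) |>
    mutate(pos = .data$pos - 1L,
           quals_plus = purrr::map(.data$quals_plus, split_quals),
           quals_minus = purrr::map(.data$quals_minus, split_quals))
  structure(pu, class = c("seqmine_pileup", class(pu)))
}
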