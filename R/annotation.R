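# Gene-model loading, site classification and coding consequences.
#
# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# 1-based inputs (GTF, VCF, SAM) are converted at the parsing boundary.

#' Load gene models into an annotation index
#'
#' Reads transcript models from a GTF (1-based, attribute keys `gene_id` and
#' `transcript_id`) or BED12 (0-based half-open) file and builds a
#' position-searchable index. All coordinates are normalized to the internal
#' 0-based half-open convention.
#'
#' @param path Path to a GTF or BED12 file.
#' @param flank_size Bases of upstream/downstream context around each
#'   transcript that still map to it (default 1000).
#' @param format `"auto"` (by file extension), `"gtf"` or `"bed"`.
#' @return An object of class `annotation_index`: a list with tibbles
#'   `transcripts` (one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`) and
#'   `exons` (one row per exon: `transcript_id`, `chrom`, `strand`, `start`,
#'   `end`), plus `flank_size`. CDS bounds are `NA` for non-coding models.
#' @export
load_gene_models <- function(path, flank_size = 1000,
                             format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  validate_gene_model_file(path, format)
  parsed <- if (format == "gtf") parse_gtf_models(path) else parse_bed12_models(path)
  new_annotation_index(parsed$transcripts, parsed$exons, flank_size)
}

validate_gene_model_file <- function(path, format) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  min_fields <- if (format == "gtf") 9L else 12L
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    coords <- if (format == "gtf") fields[4:5] else fields[c(2, 3, 7, 8, 10)]
    if (length(fields) < min_fields ||
        anyNA(suppressWarnings(as.numeric(coords)))) {
      abort(sprintf("malformed %s line %d in '%s'", toupper(format), i, path))
    }
  }
  invisible(TRUE)
}

parse_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as_tibble(as.data.frame(gr))
  assert_tbl_has(md, c("type", "gene_id", "transcript_id"), "GTF")
  ex <- filter(md, .data$type == "exon")
  if (nrow(ex) == 0 && nrow(md) > 0) {
    abort("GTF contains no exon records")
  }
  exons <- ex |>
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start = .data$start - 1L, end = as.integer(.data$end)) |>
    select("transcript_id", "chrom", "strand", "start", "end") |>
    arrange(.data$transcript_id, .data$start)
  cds_rows <- filter(md, .data$type == "CDS")
  cds <- if (nrow(cds_rows) == 0) {
    tibble(transcript_id = character(), cds_start = integer(), cds_end = integer())
  } else {
    cds_rows |>
      group_by(.data$transcript_id) |>
      summarise(cds_start = as.integer(min(.data$start)) - 1L,
                cds_end = as.integer(max(.data$end)))
  }
  transcripts <- ex |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = first(.data$gene_id),
              chrom = as.character(first(.data$seqnames)),
              strand = as.character(first(.data$strand)),
              tx_start = min(.data$start) - 1L,
              tx_end = as.integer(max(.data$end))) |>
    left_join(cds, by = "transcript_id")
  list(transcripts = transcripts, exons = exons)
}

parse_bed12_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  n_blocks <- lengths(blocks)
  if (any(n_blocks == 0)) {
    bad <- as.character(gr$name)[n_blocks == 0]
    inform(sprintf("rejected %d zero-exon BED record(s): %s",
                   length(bad), paste(bad, collapse = ", ")))
    gr <- gr[n_blocks > 0]
    blocks <- blocks[n_blocks > 0]
  }
  if (length(gr) == 0) {
    empty_tx <- tibble(transcript_id = character(), gene_id = character(),
                       chrom = character(), strand = character(),
                       tx_start = integer(), tx_end = integer(),
                       cds_start = integer(), cds_end = integer())
    empty_ex <- tibble(transcript_id = character(), chrom = character(),
                       strand = character(), start = integer(), end = integer())
    return(list(transcripts = empty_tx, exons = empty_ex))
  }
  tx_ids <- as.character(gr$name)
  exons <- purrr::map2(seq_along(gr), tx_ids, function(i, id) {
    b <- blocks[[i]]
    tibble(transcript_id = id,
           chrom = as.character(GenomeInfoDb::seqnames(gr))[i],
           strand = as.character(BiocGenerics::strand(gr))[i],
           start = BiocGenerics::start(b) - 1L,
           end = as.integer(BiocGenerics::end(b)))
  }) |> bind_rows() |> arrange(.data$transcript_id, .data$start)
  thick <- gr$thick
  cds_start <- BiocGenerics::start(thick) - 1L
  cds_end <- as.integer(BiocGenerics::end(thick))
  noncoding <- BiocGenerics::width(thick) == 0
  cds_start[noncoding] <- NA_integer_
  cds_end[noncoding] <- NA_integer_
  transcripts <- tibble(
    transcript_id = tx_ids,
    gene_id = tx_ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    tx_start = BiocGenerics::start(gr) - 1L,
    tx_end = as.integer(BiocGenerics::end(gr)),
    cds_start = cds_start,
    cds_end = cds_end)
  list(transcripts = transcripts, exons = exons)
}

new_annotation_index <- function(transcripts, exons, flank_size) {
  stopifnot(all(exons$end > exons$start | nrow(exons) == 0))
  exons_by_tx <- split(exons[c("start", "end")], exons$transcript_id)
  lookup <- split(transcripts, transcripts$chrom) |>
    purrr::map(function(tx) {
      list(ranges = IRanges::IRanges(start = tx$tx_start - flank_size + 1L,
                                     end = tx$tx_end + flank_size),
           transcript_id = tx$transcript_id)
    })
  structure(list(transcripts = transcripts, exons = exons,
                 exons_by_tx = exons_by_tx, lookup = lookup,
                 flank_size = flank_size),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index> %d transcripts, %d exons, flank %d bp\n",
              nrow(x$transcripts), nrow(x$exons), x$flank_size))
  invisible(x)
}

#' Classify a genomic position against the gene models
#'
#' Returns one row per transcript whose span (plus/minus the index's flank)
#' covers the position. A zero-row result means the position is intergenic.
#' Splice sites are the first/last 2 intronic bases of each intron.
#'
#' @param index An `annotation_index` from [load_gene_models()].
#' @param chrom Chromosome name.
#' @param pos 0-based position.
#' @return Tibble with `transcript_id`, `gene_id`, `region_category` (one of
#'   upstream, downstream, 5'UTR, 3'UTR, exon_coding, intron, splice_site,
#'   noncoding_exon) and `position_in_transcript` (1-based transcript
#'   coordinate, `NA` outside exons).
#' @export
classify_site <- function(index, chrom, pos) {
  empty <- tibble(transcript_id = character(), gene_id = character(),
                  region_category = character(),
                  position_in_transcript = integer())
  lk <- index$lookup[[chrom]]
  if (is.null(lk)) {
    note_unknown_chrom(chrom)
    return(empty)
  }
  hits <- IRanges::findOverlaps(IRanges::IRanges(pos + 1L, pos + 1L), lk$ranges)
  tx_ids <- lk$transcript_id[S4Vectors::subjectHits(hits)]
  if (length(tx_ids) == 0) return(empty)
  purrr::map(tx_ids, function(id) {
    tx <- index$transcripts[index$transcripts$transcript_id == id, ]
    classify_in_transcript(tx, index$exons_by_tx[[id]], pos)
  }) |> bind_rows()
}

# one transcript, one position
classify_in_transcript <- function(tx, exons, pos) {
  out <- tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                region_category = NA_character_,
                position_in_transcript = NA_integer_)
  plus <- tx$strand == "+"
  if (pos < tx$tx_start) {
    out$region_category <- if (plus) "upstream" else "downstream"
    return(out)
  }
  if (pos >= tx$tx_end) {
    out$region_category <- if (plus) "downstream" else "upstream"
    return(out)
  }
  in_exon <- which(exons$start <= pos & pos < exons$end)
  if (length(in_exon) == 1) {
    offset <- sum(pmax(0L, pmin(exons$end, pos) - exons$start)) # bases before pos
    total <- sum(exons$end - exons$start)
    out$position_in_transcript <- if (plus) offset + 1L else total - offset
    coding <- !is.na(tx$cds_start)
    if (!coding) {
      out$region_category <- "noncoding_exon"
    } else if (pos >= tx$cds_start && pos < tx$cds_end) {
      out$region_category <- "exon_coding"
    } else if (pos < tx$cds_start) {
      out$region_category <- if (plus) "5'UTR" else "3'UTR"
    } else {
      out$region_category <- if (plus) "3'UTR" else "5'UTR"
    }
    return(out)
  }
  # intronic: distance to the nearest exon boundary on either side
  prev_end <- max(exons$end[exons$end <= pos])
  next_start <- min(exons$start[exons$start > pos])
  splice <- (pos - prev_end) <= 1L || (next_start - 1L - pos) <= 1L
  out$region_category <- if (splice) "splice_site" else "intron"
  out
}

.seqmine_env <- new.env(parent = emptyenv())

note_unknown_chrom <- function(chrom) {
  seen <- get0("unknown_chroms", envir = .seqmine_env, ifnotfound = character())
  if (!chrom %in% seen) {
    inform(sprintf("chromosome '%s' not in annotation index; treating as intergenic", chrom))
    assign("unknown_chroms", c(seen, chrom), envir = .seqmine_env)
  }
}

#' Coding consequence of a substitution or indel inside a CDS
#'
#' @param reference_cds Coding sequence of the transcript (5'->3', length a
#'   multiple of 3).
#' @param pos_in_cds 0-based offset of the variant within the CDS.
#' @param ref Reference allele (single base for substitutions).
#' @param alt Alternate allele: a base, `"+SEQ"` for an insertion, or `"-L"`
#'   for a deletion of L bases.
#' @return Tibble with `consequence` (synonymous, missense, nonsense,
#'   frameshift, inframe_indel), `codon_number` and `amino_acid_change`.
#' @export
coding_consequence <- function(reference_cds, pos_in_cds, ref, alt) {
  nc <- nchar(reference_cds)
  if (nc %% 3 != 0) abort("reference_cds length is not divisible by 3")
  if (pos_in_cds < 0 || pos_in_cds >= nc) abort("pos_in_cds outside the CDS")
  codon_number <- pos_in_cds %/% 3 + 1L
  if (is_indel_allele(alt)) {
    len <- if (startsWith(alt, "+")) nchar(alt) - 1L else as.integer(sub("^-", "", alt))
    cons <- if (len %% 3 == 0) "inframe_indel" else "frameshift"
    return(tibble(consequence = cons, codon_number = codon_number,
                  amino_acid_change = NA_character_))
  }
  cds_ref <- substr(reference_cds, pos_in_cds + 1, pos_in_cds + 1)
  if (!identical(cds_ref, ref)) {
    abort(sprintf("reference allele mismatch at CDS position %d: CDS has %s, call says %s",
                  pos_in_cds, cds_ref, ref))
  }
  codon_start <- (codon_number - 1L) * 3L + 1L
  old_codon <- substr(reference_cds, codon_start, codon_start + 2L)
  new_codon <- old_codon
  substr(new_codon, pos_in_cds %% 3 + 1L, pos_in_cds %% 3 + 1L) <- alt
  old_aa <- Biostrings::GENETIC_CODE[[old_codon]]
  new_aa <- Biostrings::GENETIC_CODE[[new_codon]]
  consequence <- if (old_aa == new_aa) "synonymous"
    else if (new_aa == "*") "nonsense"
    else "missense"
  tibble(consequence = consequence, codon_number = codon_number,
         amino_acid_change = paste0(aa3(old_aa), "->", aa3(new_aa)))
}

#' Write an annotation index back to BED12
#'
#' @param index An `annotation_index`.
#' @param path Output file path.
#' @export
write_bed12 <- function(index, path) {
  tx <- index$transcripts
  lines <- purrr::map_chr(seq_len(nrow(tx)), function(i) {
    t <- tx[i, ]
    ex <- index$exons_by_tx[[t$transcript_id]]
    ex <- ex[order(ex$start), ]
    thick_start <- if (is.na(t$cds_start)) t$tx_start else t$cds_start
    thick_end <- if (is.na(t$cds_end)) t$tx_start else t$cds_end
    paste(t$chrom, t$tx_start, t$tx_end, t$transcript_id, 0L, t$strand,
          thick_start, thick_end, "0", nrow(ex),
          paste0(ex$end - ex$start, collapse = ","),
          paste0(ex$start - t$tx_start, collapse = ","),
          sep = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read known variant sites from a VCF file
#'
#' Only CHROM, POS, ID, REF and ALT are used. Multi-allelic records are
#' expanded; indels are converted to the package's internal allele encoding
#' (`"+SEQ"` insertions anchored at the base before, `"-L"` deletions at the
#' first deleted base).
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return Tibble with `chrom`, `pos` (0-based), `ref`, `alt`, `known_id`.
#' @export
read_known_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) {       # single record collapses to a vector
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- as_tibble(as.data.frame(fix_mat, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), known_id = character()))
  }
  fix |>
    mutate(POS = as.integer(.data$POS)) |>
    tidyr::separate_rows("ALT", sep = ",") |>
    purrr::pmap(function(CHROM, POS, ID, REF, ALT, ...) {
      normalize_vcf_allele(CHROM, POS, ID, REF, ALT)
    }) |>
    bind_rows()
}

normalize_vcf_allele <- function(chrom, pos1, id, ref, alt) {
  id <- ifelse(is.na(id) | id == ".", NA_character_, id)
  del_len <- nchar(ref) - nchar(alt)
  ins_seq <- substring(alt, nchar(ref) + 1)
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    tibble(chrom = chrom, pos = pos1 - 1L, ref = ref, alt = alt, known_id = id)
  } else if (del_len > 0) {                  # deletion, VCF-anchored
    tibble(chrom = chrom, pos = pos1, ref = substr(ref, 2, 2),
           alt = paste0("-", del_len), known_id = id)
  } else {                                   # insertion
    tibble(chrom = chrom, pos = pos1 - 1L, ref = substr(ref, 1, 1),
           alt = paste0("+", ins_seq), known_id = id)
  }
}
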