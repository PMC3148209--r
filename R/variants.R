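# Four-criterion mutation filter, genotype categories, ASE and annotation.
#
# Filter criteria (in order): base-quality masking first (bases with Phred
# below min_base_qual are removed from the coverage), then
#   coverage : effective depth >= min_coverage
#   strand   : minor-strand fraction of alt-supporting reads >= min_minor_strand_freq
#   alt_freq : alt reads / effective depth >= min_alt_freq
# All comparisons are inclusive; effective depth counts base evidence plus
# deletion-supporting reads (which cover the position without a base call).

#' Mutation filter configuration
#'
#' @param min_coverage Minimum effective read depth at a candidate site
#'   (default 20).
#' @param min_base_qual Phred threshold; lower-quality base calls are removed
#'   from the coverage before any criterion is evaluated (default 10).
#' @param min_minor_strand_freq Minimum fraction of alt-supporting reads on
#'   the minor sequenced strand (default 0.1).
#' @param min_alt_freq Minimum fraction of alt-supporting reads among all
#'   reads covering the position (default 0.25).
#' @param hom_alt_freq Alt-allele fraction at or above which a passing site is
#'   called a homozygous rather than heterozygous mutation (default 0.75).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_coverage = 20, min_base_qual = 10,
                          min_minor_strand_freq = 0.1, min_alt_freq = 0.25,
                          hom_alt_freq = 0.75) {
  fracs <- c(min_minor_strand_freq, min_alt_freq, hom_alt_freq)
  if (any(fracs < 0 | fracs > 1)) abort("fraction thresholds must be in [0, 1]")
  if (min_alt_freq >= hom_alt_freq) abort("min_alt_freq must be < hom_alt_freq")
  structure(list(min_coverage = min_coverage, min_base_qual = min_base_qual,
                 min_minor_strand_freq = min_minor_strand_freq,
                 min_alt_freq = min_alt_freq, hom_alt_freq = hom_alt_freq),
            class = "filter_config")
}

#' Remove low-quality base calls from a pileup column
#'
#' Base calls with Phred quality below `min_base_qual` are removed from the
#' tallies (counts and quality lists). Rows without recorded qualities
#' (including indel evidence) are untouched. Idempotent; a threshold of 0 is
#' the identity.
#'
#' @param col Pileup rows for one position.
#' @param min_base_qual Phred threshold.
#' @return The masked column.
#' @export
mask_quality <- function(col, min_base_qual) {
  base <- is_base_allele(col$allele)
  drop_p <- vapply(col$quals_plus,
                   function(x) sum(x < min_base_qual), integer(1))
  drop_m <- vapply(col$quals_minus,
                   function(x) sum(x < min_base_qual), integer(1))
  col$plus <- col$plus - ifelse(base, drop_p, 0L)
  col$minus <- col$minus - ifelse(base, drop_m, 0L)
  keep_q <- function(x) x[x >= min_base_qual]
  touched <- base & (drop_p + drop_m) > 0
  if (any(touched)) {
    col$quals_plus[touched] <- lapply(col$quals_plus[touched], keep_q)
    col$quals_minus[touched] <- lapply(col$quals_minus[touched], keep_q)
  }
  col[col$plus + col$minus > 0, ]
}

# Candidate alternate allele: highest-count non-reference evidence; ties
# broken A < C < G < T < indels (indels lexicographically).
candidate_alt <- function(col) {
  keep <- col$allele != col$ref[1] & col$allele != "N" &
    col$plus + col$minus > 0
  if (!any(keep)) return(NULL)
  alt_rows <- col[keep, ]
  o <- order(-(alt_rows$plus + alt_rows$minus),
             allele_rank(alt_rows$allele), alt_rows$allele)
  alt_rows[o[1], ]
}

# Effective depth: base evidence plus deletion-supporting reads.
effective_depth <- function(col) {
  sum((col$plus + col$minus)[is_base_allele(col$allele) |
                             is_deletion_allele(col$allele)])
}

#' Apply the mutation filter to one pileup column
#'
#' @param col Pileup rows for one position (one row per allele).
#' @param cfg A [filter_config()].
#' @return List with `pass` (logical), `reasons` (character vector of failed
#'   criteria among `"coverage"`, `"strand"`, `"alt_freq"`, or
#'   `"no_candidate"` when no alternate evidence survives masking), the
#'   `masked` column, and the candidate summary: `alt`, `alt_count`,
#'   `alt_plus`, `alt_minus`, `alt_freq`, `effective_depth`.
#' @export
filter_site <- function(col, cfg = filter_config()) {
  masked <- mask_quality(col, cfg$min_base_qual)
  depth <- effective_depth(masked)
  cand <- candidate_alt(masked)
  if (is.null(cand)) {
    return(list(pass = FALSE, reasons = "no_candidate", masked = masked,
                alt = NA_character_, alt_count = 0L, alt_plus = 0L,
                alt_minus = 0L, alt_freq = NA_real_, effective_depth = depth))
  }
  reasons <- character(0)
  alt_count <- cand$plus + cand$minus
  if (depth < cfg$min_coverage) reasons <- c(reasons, "coverage")
  if (depth == 0) {
    return(list(pass = FALSE, reasons = reasons, masked = masked,
                alt = cand$allele, alt_count = alt_count,
                alt_plus = cand$plus, alt_minus = cand$minus,
                alt_freq = NA_real_, effective_depth = 0L))
  }
  minor_strand <- min(cand$plus, cand$minus) / alt_count
  if (minor_strand < cfg$min_minor_strand_freq) reasons <- c(reasons, "strand")
  alt_freq <- alt_count / depth
  if (alt_freq < cfg$min_alt_freq) reasons <- c(reasons, "alt_freq")
  list(pass = length(reasons) == 0, reasons = reasons, masked = masked,
       alt = cand$allele, alt_count = alt_count, alt_plus = cand$plus,
       alt_minus = cand$minus, alt_freq = alt_freq, effective_depth = depth)
}

#' Genotype category of one pileup column
#'
#' Candidate sites passing the filter are `het_mut` or `hom_mut` (alt
#' fraction at or above `hom_alt_freq`); candidates failing it are `qc`.
#' Non-candidate positions are `hom_ref` or `qc` depending on whether the
#' effective depth reaches the coverage threshold.
#'
#' @inheritParams filter_site
#' @return One of `"hom_ref"`, `"het_mut"`, `"hom_mut"`, `"qc"`.
#' @export
call_genotype <- function(col, cfg = filter_config()) {
  fs <- filter_site(col, cfg)
  if (identical(fs$reasons, "no_candidate")) {
    return(if (fs$effective_depth >= cfg$min_coverage) "hom_ref" else "qc")
  }
  if (!fs$pass) return("qc")
  if (fs$alt_freq >= cfg$hom_alt_freq) "hom_mut" else "het_mut"
}

#' Call variants from a pileup
#'
#' Evaluates every position with alternate evidence surviving the quality
#' mask, recording the filter verdict, genotype category and per-allele ASE
#' read counts.
#'
#' @param pileup A pileup tibble from [pileup_from_sam()].
#' @param cfg A [filter_config()].
#' @return Tibble with one row per candidate site: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `effective_depth`, `alt_count`, `alt_plus`, `alt_minus`,
#'   `alt_freq`, `pass`, `genotype`, `filter_reasons` (list-column) and `ase`
#'   (list-column of named allele read counts after masking).
#' @export
call_variants <- function(pileup, cfg = filter_config()) {
  cand_pos <- pileup |>
    filter(.data$allele != .data$ref) |>
    distinct(.data$chrom, .data$pos)
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), effective_depth = integer(),
                  alt_count = integer(), alt_plus = integer(),
                  alt_minus = integer(), alt_freq = double(), pass = logical(),
                  genotype = character(), filter_reasons = list(), ase = list())
  if (nrow(cand_pos) == 0) return(empty)
  cols <- pileup |>
    inner_join(cand_pos, by = c("chrom", "pos")) |>
    group_by(.data$chrom, .data$pos)
  keys <- dplyr::group_keys(cols)
  rows <- dplyr::group_split(cols) |>
    purrr::imap(function(col, i) {
      fs <- filter_site(col, cfg)
      if (identical(fs$reasons, "no_candidate")) return(NULL)
      ase_counts <- setNames(fs$masked$plus + fs$masked$minus, fs$masked$allele)
      genotype <- if (!fs$pass) "qc"
        else if (fs$alt_freq >= cfg$hom_alt_freq) "hom_mut" else "het_mut"
      tibble(chrom = keys$chrom[i], pos = keys$pos[i], ref = col$ref[1],
             alt = fs$alt, effective_depth = as.integer(fs$effective_depth),
             alt_count = as.integer(fs$alt_count),
             alt_plus = as.integer(fs$alt_plus),
             alt_minus = as.integer(fs$alt_minus),
             alt_freq = fs$alt_freq, pass = fs$pass, genotype = genotype,
             filter_reasons = list(fs$reasons[fs$reasons != ""]),
             ase = list(ase_counts))
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Annotate variant calls with gene models and known sites
#'
#' Produces one row per (call x overlapping transcript); calls overlapping no
#' transcript get a single `intergenic` row. Coding consequences are computed
#' for substitutions and indels inside a CDS when the reference genome is
#' supplied (alleles on minus-strand transcripts are reverse-complemented
#' before codon lookup). `known_id` is filled on exact
#' (chrom, pos, ref, alt) match against the known-site table.
#'
#' @param calls A call tibble from [call_variants()].
#' @param index An `annotation_index`.
#' @param known_sites Optional tibble from [read_known_sites()].
#' @param reference Optional named character vector (or FASTA path) with the
#'   reference genome, needed for coding consequences.
#' @return The calls joined with `transcript_id`, `gene_id`,
#'   `region_category`, `position_in_transcript`, `consequence`,
#'   `codon_number`, `amino_acid_change`, `known_id`.
#' @export
annotate_calls <- function(calls, index, known_sites = NULL, reference = NULL) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- read_reference(reference)
  }
  ann <- purrr::map(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    regions <- classify_site(index, call$chrom, call$pos)
    if (nrow(regions) == 0) {
      regions <- tibble(transcript_id = NA_character_, gene_id = NA_character_,
                        region_category = "intergenic",
                        position_in_transcript = NA_integer_)
    }
    cons <- purrr::pmap(regions, function(transcript_id, region_category, ...) {
      if (region_category != "exon_coding" || is.null(reference)) {
        return(tibble(consequence = if (region_category == "exon_coding")
                        NA_character_ else "none",
                      codon_number = NA_integer_,
                      amino_acid_change = NA_character_))
      }
      consequence_for_call(call, index, transcript_id, reference)
    }) |> bind_rows()
    bind_rows(replicate(nrow(regions), call, simplify = FALSE)) |>
      bind_cols(regions, cons)
  }) |> bind_rows()
  if (!is.null(known_sites)) {
    ann <- left_join(ann,
                     rename(known_sites, known_pos = "pos") |>
                       select("chrom", pos = "known_pos", "ref", "alt", "known_id"),
                     by = c("chrom", "pos", "ref", "alt"))
  } else {
    ann$known_id <- NA_character_
  }
  ann
}

consequence_for_call <- function(call, index, transcript_id, reference) {
  na_row <- tibble(consequence = NA_character_, codon_number = NA_integer_,
                   amino_acid_change = NA_character_)
  tx <- index$transcripts[index$transcripts$transcript_id == transcript_id, ]
  ex <- index$exons_by_tx[[transcript_id]]
  cds_pos <- cds_genomic_positions(ex, tx$cds_start, tx$cds_end)
  if (length(cds_pos) %% 3 != 0) {
    warn(sprintf("CDS length of %s not divisible by 3; consequence skipped",
                 transcript_id))
    return(na_row)
  }
  chrom_seq <- reference[[tx$chrom]]
  cds_bases <- substring(chrom_seq, cds_pos + 1L, cds_pos + 1L)
  minus <- tx$strand == "-"
  cds_seq <- if (minus) revcomp(paste(cds_bases, collapse = ""))
             else paste(cds_bases, collapse = "")
  pos_in_cds <- if (minus) sum(cds_pos > call$pos) else sum(cds_pos < call$pos)
  ref <- call$ref; alt <- call$alt
  if (is_base_allele(alt) && minus) {
    ref <- revcomp(ref); alt <- revcomp(alt)
  }
  tryCatch(coding_consequence(cds_seq, pos_in_cds, ref, alt),
           error = function(e) { warn(conditionMessage(e)); na_row })
}

cds_genomic_positions <- function(exons, cds_start, cds_end) {
  pos <- purrr::map2(exons$start, exons$end, function(s, e) {
    s2 <- max(s, cds_start); e2 <- min(e, cds_end)
    if (s2 < e2) seq.int(s2, e2 - 1L) else integer(0)
  })
  sort(unlist(pos))
}
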