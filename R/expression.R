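# Coverage tracks, exome QC, RPKM quantification and expression matrices.

#' Per-base coverage track from SAM alignments
#'
#' Depth at a base is the number of kept reads whose aligned span (CIGAR
#' M/=/X/D) covers it; N (skip) gaps contribute nothing, so RNA splice gaps
#' are excluded while exome deletions still count as covered.
#'
#' @param sam Path to a coordinate-sorted SAM file or a read tibble.
#' @param chrom_lengths Named integer vector of chromosome lengths, or a
#'   reference FASTA path / named sequence vector from which lengths are taken.
#' @param min_mapq Minimum mapping quality (default 10).
#' @return A `coverage_track`: named list of integer depth vectors, one per
#'   chromosome, each of the chromosome's length.
#' @export
coverage_track <- function(sam, chrom_lengths, min_mapq = 10) {
  reads <- if (is.character(sam)) read_sam(sam) else sam
  if (is.character(chrom_lengths) && length(chrom_lengths) == 1 &&
      file.exists(chrom_lengths)) {
    chrom_lengths <- nchar(read_reference(chrom_lengths))
  } else if (is.character(chrom_lengths)) {
    chrom_lengths <- nchar(chrom_lengths)
  }
  reads <- filter(reads, .data$mapq >= min_mapq)
  missing_chrom <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome(s) absent from reference: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  track <- purrr::imap(as.list(chrom_lengths), function(len, chrom) {
    rd <- filter(reads, .data$chrom == !!chrom)
    if (nrow(rd) == 0) return(integer(len))
    iv <- purrr::map2(rd$pos, rd$cigar, aligned_intervals) |> bind_rows()
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    as.integer(IRanges::coverage(ir, width = len))
  })
  structure(track, class = "coverage_track")
}

#' Write / read a coverage track in WIG format
#'
#' Writes UCSC fixedStep WIG, `step=1`, one block per chromosome starting at
#' base 1. `read_wig()` restores the track exactly.
#'
#' @param track A `coverage_track`.
#' @param path File path.
#' @return `write_wig()` the path, invisibly; `read_wig()` a `coverage_track`.
#' @export
write_wig <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track type=wiggle_0", con)
  for (chrom in names(track)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
    writeLines(format(track[[chrom]], scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_wig
#' @export
read_wig <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  heads <- grep("^fixedStep", lines)
  if (length(heads) == 0) abort("no fixedStep blocks found")
  bounds <- c(heads, length(lines) + 1L)
  track <- purrr::map(seq_along(heads), function(i) {
    h <- lines[heads[i]]
    start <- as.integer(sub(".*start=(\\d+).*", "\\1", h))
    step <- as.integer(sub(".*step=(\\d+).*", "\\1", h))
    if (step != 1) abort("only step=1 fixedStep WIG is supported")
    vals <- as.numeric(lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)])
    c(rep(0, start - 1L), vals)
  })
  names(track) <- sub(".*chrom=(\\S+).*", "\\1", lines[heads])
  structure(purrr::map(track, ~ if (all(.x == round(.x))) as.integer(.x) else .x),
            class = "coverage_track")
}

#' Exome coverage quality-control report
#'
#' Per-exon average coverage is summed depth over the exon divided by exon
#' length; exons are the distinct exon intervals of the gene models. `mde` is
#' the mean of those averages, `ec5`/`ec10` the percentage of exons with
#' average coverage of at least 5/10 fold (coverage sensitivity), and
#' specificity the percentage of mapped reads on target exons.
#'
#' @param track A `coverage_track`.
#' @param index An `annotation_index`.
#' @param total_mapped_reads Number of mapped reads in the sample.
#' @param on_target_reads Number of mapped reads overlapping the exon set.
#' @param defective_floor Exons with average coverage below this are reported
#'   as defective (default 5).
#' @return An `exon_qc_report` with `mde`, `ec5`, `ec10`,
#'   `coverage_specificity`, `coverage_quantiles`, `defective_regions` and
#'   the per-exon coverage table. Use [generics::glance()] for the one-row
#'   summary and [generics::tidy()] for the per-exon table.
#' @export
exon_qc <- function(track, index, total_mapped_reads, on_target_reads,
                    defective_floor = 5) {
  if (total_mapped_reads <= 0) abort("total_mapped_reads must be > 0")
  exons <- distinct(index$exons, .data$chrom, .data$start, .data$end)
  if (nrow(exons) == 0) abort("annotation index has no exons")
  exons <- exons |>
    mutate(avg_coverage = purrr::pmap_dbl(list(.data$chrom, .data$start, .data$end),
      function(chrom, start, end) {
        depth <- track[[chrom]]
        if (is.null(depth)) return(0)
        sum(depth[(start + 1L):min(end, length(depth))]) / (end - start)
      }),
      defective = .data$avg_coverage < defective_floor)
  structure(list(
    mde = mean(exons$avg_coverage),
    ec5 = 100 * mean(exons$avg_coverage >= 5),
    ec10 = 100 * mean(exons$avg_coverage >= 10),
    coverage_specificity = 100 * on_target_reads / total_mapped_reads,
    coverage_quantiles = quantile(exons$avg_coverage, c(0, .25, .5, .75, 1)),
    defective_regions = filter(exons, .data$defective),
    exons = exons,
    total_mapped_reads = total_mapped_reads,
    on_target_reads = on_target_reads
  ), class = "exon_qc_report")
}

#' @export
print.exon_qc_report <- function(x, ...) {
  cat(sprintf("<exon_qc_report> %d exons | mde %.1f | ec5 %.1f%% | ec10 %.1f%% | specificity %.1f%%\n",
              nrow(x$exons), x$mde, x$ec5, x$ec10, x$coverage_specificity))
  invisible(x)
}

#' Count reads overlapping transcript exon unions
#'
#' A read is counted once for every feature whose exon union its aligned
#' (M/=/X) span overlaps.
#'
#' @param reads Read tibble (already mapq-filtered if desired).
#' @param index An `annotation_index`.
#' @param level `"transcript"` (exon union per transcript) or `"exon"`
#'   (distinct exon intervals, feature id `chrom:start-end`).
#' @return Tibble with `feature_id`, `chrom`, `start`, `end`, `length`
#'   (model length in bases) and `read_count`.
#' @export
count_reads <- function(reads, index, level = c("transcript", "exon")) {
  level <- match.arg(level)
  feats <- if (level == "transcript") {
    index$exons |>
      group_by(feature_id = .data$transcript_id, .data$chrom) |>
      summarise(length = sum(.data$end - .data$start),
                start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      select("feature_id", "chrom", "start", "end", "length")
  } else {
    distinct(index$exons, .data$chrom, .data$start, .data$end) |>
      mutate(feature_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
             length = .data$end - .data$start)
  }
  read_iv <- purrr::map(seq_len(nrow(reads)), function(i) {
    aligned_intervals(reads$pos[i], reads$cigar[i], ops = c("M", "=", "X")) |>
      mutate(read = i, chrom = reads$chrom[i])
  }) |> bind_rows()
  feats$read_count <- 0L
  for (chrom in unique(feats$chrom)) {
    fi <- which(feats$chrom == chrom)
    ri <- read_iv[read_iv$chrom == chrom, , drop = FALSE]
    if (nrow(ri) == 0) next
    rr <- IRanges::IRanges(start = ri$start + 1L, end = ri$end)
    for (k in fi) {
      ex <- if (level == "transcript") {
        e <- index$exons[index$exons$transcript_id == feats$feature_id[k], ]
        IRanges::IRanges(start = e$start + 1L, end = e$end)
      } else {
        IRanges::IRanges(start = feats$start[k] + 1L, end = feats$end[k])
      }
      hits <- IRanges::findOverlaps(rr, ex)
      feats$read_count[k] <- length(unique(ri$read[S4Vectors::queryHits(hits)]))
    }
  }
  select(feats, "feature_id", "chrom", "start", "end", "length", "read_count")
}

#' RPKM from read counts and model lengths
#'
#' `rpkm = count / (length/1000) / (total_mapped_reads/1e6)` — reads per
#' kilobase of exon model per million mapped reads.
#'
#' @param counts Tibble with `feature_id`, `length` (bases) and `read_count`,
#'   e.g. from [count_reads()]. Extra columns are carried through.
#' @param total_mapped_reads Number of mapped reads in the sample (reads
#'   passing the mapping-quality filter, not the library size).
#' @param aligned_bases Optional named vector (by `feature_id`) of aligned
#'   bases falling on each model, used for `mean_coverage`.
#' @return The input with `rpkm` (and `mean_coverage` when computable) added.
#' @export
rpkm_quantify <- function(counts, total_mapped_reads, aligned_bases = NULL) {
  assert_tbl_has(counts, c("feature_id", "length", "read_count"), "counts")
  if (total_mapped_reads <= 0) abort("total_mapped_reads must be > 0")
  if (any(counts$length <= 0)) abort("zero-length model in counts")
  out <- mutate(counts, rpkm = .data$read_count / (.data$length / 1000) /
                  (total_mapped_reads / 1e6))
  if (!is.null(aligned_bases)) {
    out$mean_coverage <- unname(aligned_bases[out$feature_id]) / out$length
  }
  out
}

#' Quantify one sample end to end
#'
#' Counts reads on transcript or exon models, computes mean coverage from the
#' coverage track and RPKM from the mapped-read total.
#'
#' @param reads Read tibble or SAM path.
#' @param index An `annotation_index`.
#' @param chrom_lengths As in [coverage_track()].
#' @param min_mapq Minimum mapping quality (default 10).
#' @param level `"transcript"` or `"exon"`.
#' @return Tibble with `feature_id`, `chrom`, `start`, `end`, `length`,
#'   `read_count`, `mean_coverage`, `rpkm`.
#' @export
quantify_sample <- function(reads, index, chrom_lengths, min_mapq = 10,
                            level = c("transcript", "exon")) {
  level <- match.arg(level)
  if (is.character(reads)) reads <- read_sam(reads)
  reads <- filter(reads, .data$mapq >= min_mapq)
  track <- coverage_track(reads, chrom_lengths, min_mapq = 0)
  counts <- count_reads(reads, index, level = level)
  counts$mean_coverage <- purrr::map_dbl(counts$feature_id, function(fid) {
    if (level == "transcript") {
      e <- index$exons[index$exons$transcript_id == fid, ]
    } else {
      e <- counts[counts$feature_id == fid, c("chrom", "start", "end")]
    }
    covered <- sum(purrr::pmap_dbl(list(e$chrom, e$start, e$end),
      function(chrom, start, end) {
        depth <- track[[chrom]]
        if (is.null(depth)) 0 else sum(depth[(start + 1L):min(end, length(depth))])
      }))
    covered / sum(e$end - e$start)
  })
  rpkm_quantify(counts, total_mapped_reads = nrow(reads))
}

#' Combine per-sample expression records into an expression matrix
#'
#' Features are the union across samples; missing features get count 0 and
#' RPKM 0 (structural zeros). Sample input order does not affect content.
#'
#' @param records Named list of per-sample tibbles with `feature_id`,
#'   `read_count`, `rpkm`.
#' @return A wide tibble, `feature_id` plus one RPKM column per sample,
#'   ordered by feature; the matching read-count tibble is in
#'   `attr(, "counts")`.
#' @export
phenotype_matrix <- function(records) {
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids))) abort("`records` must be a named list")
  if (anyDuplicated(ids) > 0) abort("duplicate sample id in `records`")
  long <- purrr::imap(records, ~ mutate(select(.x, "feature_id", "read_count", "rpkm"),
                                        sample = .y)) |>
    bind_rows()
  rpkm <- long |>
    select("feature_id", "sample", "rpkm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "rpkm",
                       values_fill = 0, names_sort = TRUE) |>
    arrange(.data$feature_id)
  counts <- long |>
    select("feature_id", "sample", "read_count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "read_count",
                       values_fill = 0L, names_sort = TRUE) |>
    arrange(.data$feature_id)
  attr(rpkm, "counts") <- counts
  rpkm
}

#' Write / read an expression matrix as TSV
#'
#' @param m Expression matrix tibble (`feature_id` + one column per sample).
#' @param path File path.
#' @return `write_expression_matrix()` the path, invisibly;
#'   `read_expression_matrix()` the matrix tibble.
#' @export
write_expression_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(feature_id = "c", .default = "d"))
}
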