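# Cross-sample genotype aggregation, family-wise filtering and trio
# Mendelian-error quality control.
#
# A genotype matrix is a tibble keyed by (chrom, pos, ref, alt) with one
# column per sample holding the category: hom_ref / het_mut / hom_mut / qc.

#' Aggregate per-sample genotype calls into a genotype matrix
#'
#' Takes the union of variant keys across samples. A sample without a call at
#' a key is re-evaluated from its pileup: `hom_ref` when the effective depth
#' (after quality masking) reaches the coverage threshold, `qc` otherwise.
#' When no pileup is available for a sample the cell is `qc`.
#'
#' @param calls Named list of per-sample call tibbles. Each needs `chrom`,
#'   `pos`, `ref`, `alt`, `genotype`.
#' @param pileups Optional named list of per-sample pileup tibbles used to
#'   back-fill missing cells.
#' @param cfg A [filter_config()].
#' @return Tibble with key columns `chrom`, `pos`, `ref`, `alt` and one
#'   category column per sample, ordered by (chrom, pos, alt).
#' @export
aggregate_genotypes <- function(calls, pileups = NULL, cfg = filter_config()) {
  if (length(calls) == 0) abort("at least one sample is required")
  ids <- names(calls)
  if (is.null(ids) || any(!nzchar(ids))) abort("`calls` must be a named list")
  if (anyDuplicated(ids) > 0) abort("duplicate sample id in `calls`")
  keys <- purrr::map(calls, ~ filter(.x, .data$genotype %in% c("het_mut", "hom_mut")) |>
                       select("chrom", "pos", "ref", "alt")) |>
    bind_rows() |>
    distinct() |>
    arrange(.data$chrom, .data$pos, .data$alt)
  if (nrow(keys) == 0) return(keys)
  for (id in ids) {
    cell <- calls[[id]] |>
      select("chrom", "pos", "ref", "alt", "genotype") |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
    keys <- left_join(keys, rename(cell, !!id := "genotype"),
                      by = c("chrom", "pos", "ref", "alt"))
    missing <- is.na(keys[[id]])
    if (any(missing)) {
      keys[[id]][missing] <- backfill_category(
        keys[missing, c("chrom", "pos")], pileups[[id]], cfg)
    }
  }
  keys
}

backfill_category <- function(sites, pileup, cfg) {
  if (is.null(pileup)) return(rep("qc", nrow(sites)))
  purrr::map_chr(seq_len(nrow(sites)), function(i) {
    col <- filter(pileup, .data$chrom == sites$chrom[i], .data$pos == sites$pos[i])
    if (nrow(col) == 0) return("qc")
    depth <- effective_depth(mask_quality(col, cfg$min_base_qual))
    if (depth >= cfg$min_coverage) "hom_ref" else "qc"
  })
}

#' Read a pedigree file of trios
#'
#' One trio per line: `father<TAB>mother<TAB>child`.
#'
#' @param path Path to the pedigree TSV (no header).
#' @return Tibble with `father`, `mother`, `child`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_names = c("father", "mother", "child"),
                         col_types = "ccc")
  bad <- purrr::map_lgl(seq_len(nrow(ped)),
                        ~ anyDuplicated(unlist(ped[.x, ])) > 0)
  if (any(bad)) abort("pedigree contains a trio with duplicated sample ids")
  ped
}

#' Family-wise genotype filter
#'
#' Removes every row in which at least one member of any trio is `qc`,
#' leaving all other rows unchanged.
#'
#' @param m Genotype matrix from [aggregate_genotypes()].
#' @param ped Pedigree tibble (`father`, `mother`, `child`).
#' @return The filtered genotype matrix.
#' @export
family_filter <- function(m, ped) {
  members <- unique(unlist(ped[c("father", "mother", "child")]))
  missing <- setdiff(members, names(m))
  if (length(missing) > 0) {
    abort(sprintf("pedigree sample(s) not in matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  any_qc <- rowSums(as.matrix(m[members]) == "qc") > 0
  m[!any_qc, ]
}

#' Mendelian consistency of one genotype triple
#'
#' Categories map to biallelic genotypes (hom_ref = RR, het_mut = RA,
#' hom_mut = AA); a child is consistent when its two alleles can be drawn one
#' from each parent.
#'
#' @param father,mother,child Genotype categories (vectorized).
#' @return Character vector, `"consistent"` or `"mendelian_error"`.
#' @export
check_trio <- function(father, mother, child) {
  if (any(c(father, mother, child) == "qc")) {
    abort("check_trio requires qc-free genotypes; run family_filter() first")
  }
  alleles <- list(hom_ref = c(0L, 0L), het_mut = c(0L, 1L), hom_mut = c(1L, 1L))
  purrr::pmap_chr(list(father, mother, child), function(f, m, c) {
    fa <- alleles[[f]]; ma <- alleles[[m]]; ch <- sort(alleles[[c]])
    ok <- FALSE
    for (x in unique(fa)) for (y in unique(ma)) {
      if (identical(sort(c(x, y)), ch)) ok <- TRUE
    }
    if (ok) "consistent" else "mendelian_error"
  })
}

#' Per-sample Mendelian error rates over a trio genotype matrix
#'
#' For each sample the denominator is the set of rows in which that sample
#' carries a mutation (`het_mut` or `hom_mut`); `failed` are the rows whose
#' trio verdict is a Mendelian error, and `rate = failed / (passed + failed)`.
#' Samples with no mutated rows get an `NA` rate.
#'
#' @param m Family-filtered genotype matrix.
#' @param ped Pedigree tibble.
#' @return Tibble with `sample`, `role`, `passed`, `failed`, `rate`.
#' @export
mendelian_error_rate <- function(m, ped) {
  purrr::pmap(ped, function(father, mother, child) {
    verdict <- check_trio(m[[father]], m[[mother]], m[[child]])
    purrr::map2(c(father, mother, child), c("father", "mother", "child"),
                function(id, role) {
      mutated <- m[[id]] %in% c("het_mut", "hom_mut")
      passed <- sum(mutated & verdict == "consistent")
      failed <- sum(mutated & verdict == "mendelian_error")
      tibble(sample = id, role = role, passed = passed, failed = failed,
             rate = if (passed + failed == 0) NA_real_
                    else failed / (passed + failed))
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Write / read a genotype matrix as TSV
#'
#' @param m Genotype matrix.
#' @param path File path.
#' @return `write_genotype_matrix()` the path, invisibly;
#'   `read_genotype_matrix()` the matrix tibble.
#' @export
write_genotype_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", .default = "c"))
}
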