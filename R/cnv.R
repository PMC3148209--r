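# Exon-level copy-number analysis: log2 probe signals against a reference
# sample and circular binary segmentation (CBS).
#
# CBS here is the max-statistic circular split with a permutation test: on a
# segment of k probes every arc (i, j] is scored by the normalized difference
# between the arc mean and the complement mean,
#   Z(i,j) = (mean_arc - mean_complement) / sqrt(1/n1 + 1/n2),
# the arc maximizing |Z| is the candidate split, and the split is accepted
# when the permutation p-value (1 + #exceedances)/(1 + n_perm) falls below
# alpha. Accepted splits recurse into the up-to-three resulting pieces. This
# is the published procedure without its pruning/undo refinements, which is
# adequate at exon-probe scale.

#' Log2 probe signals from sample and reference RPKM
#'
#' One probe per exon: `log2((sample_rpkm + c) / (reference_rpkm + c))`. The
#' reference may be a single normal sample or the per-exon mean of a pool
#' (averaged on the RPKM scale before the log).
#'
#' @param sample_rpkm,reference_rpkm Exon-level expression tibbles with
#'   `feature_id`, `chrom`, `start`, `end`, `rpkm`; both must cover the same
#'   exon set.
#' @param pseudocount Added to numerator and denominator (default 0.5),
#'   keeping every signal finite.
#' @return Tibble of probes ordered by (chrom, start): `chrom`, `start`,
#'   `end`, `feature_id`, `value`.
#' @export
log2_probe_signals <- function(sample_rpkm, reference_rpkm, pseudocount = 0.5) {
  assert_tbl_has(sample_rpkm, c("feature_id", "chrom", "start", "end", "rpkm"),
                 "sample_rpkm")
  sym_diff <- length(setdiff(sample_rpkm$feature_id, reference_rpkm$feature_id)) +
    length(setdiff(reference_rpkm$feature_id, sample_rpkm$feature_id))
  if (sym_diff > 0) {
    abort(sprintf("sample and reference exon sets differ by %d feature(s)", sym_diff))
  }
  sample_rpkm |>
    inner_join(select(reference_rpkm, "feature_id", ref_rpkm = "rpkm"),
               by = "feature_id") |>
    mutate(value = log2((.data$rpkm + pseudocount) /
                        (.data$ref_rpkm + pseudocount))) |>
    select("chrom", "start", "end", "feature_id", "value") |>
    arrange(.data$chrom, .data$start)
}

#' Segment probe signals by circular binary segmentation
#'
#' @param signals Probe tibble from [log2_probe_signals()] (`chrom`, `start`,
#'   `end`, `value`), at least one probe per chromosome.
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Number of permutations per candidate split (default 1000; a
#'   warning is raised below 100 since p-values become unstable).
#' @param seed Optional integer seed for the permutation stream.
#' @param sample_id Sample name written into the segment table.
#' @return A `cbs_segments` tibble: `sample`, `chrom`, `start`, `end`
#'   (0-based half-open, covering member probes), `num_probes`,
#'   `segment_mean`; probe values are kept in `attr(, "signals")`.
#' @export
cbs_segment <- function(signals, alpha = 0.01, n_perm = 1000, seed = NULL,
                        sample_id = "sample") {
  assert_tbl_has(signals, c("chrom", "start", "end", "value"), "signals")
  if (n_perm < 100) warn("n_perm < 100 gives unstable permutation p-values")
  run <- function() {
    signals |>
      arrange(.data$chrom, .data$start) |>
      group_by(.data$chrom) |>
      dplyr::group_map(function(probes, key) {
        pieces <- cbs_recurse(probes$value, alpha, n_perm)
        purrr::map(pieces, function(idx) {
          tibble(sample = sample_id, chrom = key$chrom[[1]],
                 start = probes$start[idx[1]],
                 end = probes$end[idx[length(idx)]],
                 num_probes = length(idx),
                 segment_mean = mean(probes$value[idx]))
        }) |> bind_rows()
      }) |> bind_rows()
  }
  segs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(segs, class = c("cbs_segments", class(segs)), signals = signals)
}

# Returns a list of index vectors partitioning 1..length(x), in order.
cbs_recurse <- function(x, alpha, n_perm) {
  k <- length(x)
  if (k < 2 || sd(x) == 0) return(list(seq_len(k)))
  split <- cbs_best_split(x, alpha, n_perm)
  if (is.null(split)) return(list(seq_len(k)))
  i <- split[1]; j <- split[2]
  bounds <- unique(c(0L, i, j, k))
  pieces <- purrr::map2(head(bounds, -1), tail(bounds, -1), ~ seq.int(.x + 1L, .y))
  purrr::map(pieces, function(idx) {
    purrr::map(cbs_recurse(x[idx], alpha, n_perm), ~ idx[.x])
  }) |> purrr::flatten()
}

# Candidate arc (i, j] maximizing |Z|, accepted by permutation; NULL when not
# significant. Uses sequential early stopping: once the exceedance count
# guarantees p >= alpha the scan aborts.
cbs_best_split <- function(x, alpha, n_perm) {
  k <- length(x)
  # enumerate valid arcs (i, j], 0 <= i < j <= k, excluding the full segment
  grid <- which(upper.tri(matrix(TRUE, k + 1, k + 1)), arr.ind = TRUE)
  i <- grid[, 1] - 1L
  j <- grid[, 2] - 1L
  keep <- !(i == 0L & j == k)
  i <- i[keep]; j <- j[keep]
  n1 <- j - i
  n2 <- k - n1
  w <- 1 / sqrt(1 / n1 + 1 / n2)
  max_stat <- function(v) {
    s <- c(0, cumsum(v))
    arc <- s[j + 1L] - s[i + 1L]
    max(abs((arc / n1 - (s[k + 1L] - arc) / n2) * w))
  }
  s <- c(0, cumsum(x))
  arc <- s[j + 1L] - s[i + 1L]
  z_obs <- abs((arc / n1 - (s[k + 1L] - arc) / n2) * w)
  obs <- max(z_obs)
  stop_at <- ceiling(alpha * (n_perm + 1))  # exceedances making p >= alpha
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (max_stat(sample(x)) >= obs) exceed <- exceed + 1L
    if (exceed >= stop_at) return(NULL)
  }
  p <- (1 + exceed) / (1 + n_perm)
  if (p >= alpha) return(NULL)
  best <- which.max(z_obs)
  c(i = i[best], j = j[best])
}

#' Write / read segments in .seg format
#'
#' Tab-delimited with header
#' `Sample Chromosome Start End Num_Probes Segment_Mean`; coordinates are
#' written 1-based inclusive for IGV compatibility and segment means with 4
#' decimal places.
#'
#' @param segments A `cbs_segments` tibble.
#' @param path File path.
#' @return `write_seg()` the path, invisibly; `read_seg()` a segment tibble
#'   with the package's 0-based half-open coordinates.
#' @export
write_seg <- function(segments, path) {
  lines <- c(
    paste("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean",
          sep = "\t"),
    sprintf("%s\t%s\t%d\t%d\t%d\t%.4f",
            segments$sample, segments$chrom, segments$start + 1L,
            segments$end, segments$num_probes, segments$segment_mean))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  readr::read_tsv(path, col_types = "cciid") |>
    rename(sample = "Sample", chrom = "Chromosome", start = "Start",
           end = "End", num_probes = "Num_Probes",
           segment_mean = "Segment_Mean") |>
    mutate(start = .data$start - 1L)
}
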