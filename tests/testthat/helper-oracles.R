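# Fixture builders and independent oracles used across the test files.
# Oracles are written directly from first principles and never call the
# package code paths they check.

# ---- pileup column fixtures -------------------------------------------------

# Build one pileup column (tibble of allele rows) from allele = list(plus,
# minus, quals_plus, quals_minus). Quality lists default to high-quality
# calls matching the counts.
make_col <- function(ref, alleles, chrom = "chr1", pos = 100L,
                     with_quals = TRUE) {
  rows <- purrr::imap(alleles, function(a, name) {
    qp <- a$quals_plus %||% (if (with_quals && !grepl("^[+-]", name))
      rep(35L, a$plus) else integer(0))
    qm <- a$quals_minus %||% (if (with_quals && !grepl("^[+-]", name))
      rep(35L, a$minus) else integer(0))
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, allele = name,
                   plus = as.integer(a$plus), minus = as.integer(a$minus),
                   quals_plus = list(as.integer(qp)),
                   quals_minus = list(as.integer(qm)))
  })
  dplyr::bind_rows(rows)
}

# Random pileup column with 1-3 alternate alleles (bases and occasional
# indels), random strand splits and random per-base qualities.
random_column <- function(ref = sample(c("A", "C", "G", "T"), 1)) {
  alt_pool <- c(setdiff(c("A", "C", "G", "T"), ref), "+AC", "-2")
  alleles <- c(ref, sample(alt_pool, sample(1:3, 1)))
  n <- c(sample(0:30, 1), sample(0:25, length(alleles) - 1, replace = TRUE))
  keep <- n > 0
  if (!any(keep)) { keep[1] <- TRUE; n[1] <- 1L }
  alleles <- alleles[keep]; n <- n[keep]
  p <- rbinom(length(n), n, runif(length(n), 0.1, 0.9))
  indel <- grepl("^[+-]", alleles)
  qp <- lapply(seq_along(n), function(i)
    if (indel[i]) integer(0) else sample(2:40, p[i], replace = TRUE))
  qm <- lapply(seq_along(n), function(i)
    if (indel[i]) integer(0) else sample(2:40, n[i] - p[i], replace = TRUE))
  k <- length(alleles)
  tibble::new_tibble(list(chrom = rep("chr1", k), pos = rep(100L, k),
                          ref = rep(ref, k), allele = alleles,
                          plus = as.integer(p), minus = as.integer(n - p),
                          quals_plus = qp, quals_minus = qm), nrow = k)
}

# ---- independent four-criterion filter checker ------------------------------
# Re-states the published filter rules directly on the raw column:
#  mask low-quality base calls, find the most frequent non-reference allele
#  (ties A<C<G<T<indel), then require coverage, strand balance and mutated
#  base frequency.
oracle_filter <- function(col, min_coverage = 20, min_base_qual = 10,
                          min_minor_strand_freq = 0.1, min_alt_freq = 0.25) {
  ref <- col$ref[1]
  tally <- list()
  for (r in seq_len(nrow(col))) {
    a <- col$allele[r]
    if (grepl("^[+-]", a)) {
      p <- col$plus[r]; m <- col$minus[r]
    } else {
      qp <- col$quals_plus[[r]]; qm <- col$quals_minus[[r]]
      p <- col$plus[r] - sum(qp < min_base_qual)
      m <- col$minus[r] - sum(qm < min_base_qual)
    }
    if (p + m > 0) tally[[a]] <- c(plus = p, minus = m)
  }
  names_t <- names(tally)
  covered <- vapply(names_t, function(a) !startsWith(a, "+"), logical(1))
  depth <- sum(vapply(tally[covered], sum, numeric(1)))
  alt_names <- setdiff(names_t, c(ref, "N"))
  if (length(alt_names) == 0) {
    return(list(candidate = FALSE, pass = FALSE, reasons = "no_candidate"))
  }
  counts <- vapply(tally[alt_names], sum, numeric(1))
  rank <- match(alt_names, c("A", "C", "G", "T"))
  rank[is.na(rank)] <- 5
  ord <- order(-counts, rank, alt_names)
  alt <- alt_names[ord[1]]
  reasons <- character(0)
  if (depth < min_coverage) reasons <- c(reasons, "coverage")
  if (depth > 0) {
    ac <- sum(tally[[alt]])
    if (min(tally[[alt]]) / ac < min_minor_strand_freq) {
      reasons <- c(reasons, "strand")
    }
    if (ac / depth < min_alt_freq) reasons <- c(reasons, "alt_freq")
  }
  list(candidate = TRUE, pass = length(reasons) == 0, reasons = reasons,
       alt = alt, depth = depth)
}

# ---- exhaustive Mendelian transmission oracle -------------------------------
oracle_trio <- function(father, mother, child) {
  pair <- list(hom_ref = c(0, 0), het_mut = c(0, 1), hom_mut = c(1, 1))
  fa <- pair[[father]]; ma <- pair[[mother]]; ch <- sort(pair[[child]])
  for (i in 1:2) for (j in 1:2) {
    if (identical(sort(c(fa[i], ma[j])), ch)) return("consistent")
  }
  "mendelian_error"
}

# ---- breadth-first-search all-pairs distance oracle -------------------------
oracle_bfs_distances <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(setNames(nodes, nodes),
                function(v) edges$target[edges$source == v])
  d <- matrix(n, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- setNames(rep(NA_integer_, n), nodes)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- ifelse(is.na(dist), n, dist)
  }
  d
}

# ---- tiny gene-model writers ------------------------------------------------
write_test_gtf <- function(path, rows) {
  lines <- purrr::pmap_chr(rows, function(chrom, type, start, end, strand,
                                          gene_id, transcript_id) {
    sprintf("%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            chrom, type, start, end, strand, gene_id, transcript_id)
  })
  writeLines(lines, path)
  path
}

# random transcript models (non-overlapping exons) for property tests
random_annotation_rows <- function(n_tx = 8, chrom_len = 50000) {
  purrr::map(seq_len(n_tx), function(t) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(100, chrom_len - 2000, by = 10), n_ex))
    widths <- sample(30:300, n_ex, replace = TRUE)
    ends <- pmin(starts + widths, c(starts[-1] - 10, chrom_len))
    strand <- sample(c("+", "-"), 1)
    id <- sprintf("tx%02d", t)
    rows <- tibble::tibble(chrom = "chr1", type = "exon", start = starts,
                           end = ends, strand = strand,
                           gene_id = sprintf("g%02d", t), transcript_id = id)
    if (runif(1) < 0.7 && sum(ends - starts + 1) > 60) {
      cs <- starts[1] + 5
      ce <- ends[n_ex] - 5
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        chrom = "chr1", type = "CDS", start = cs, end = ce, strand = strand,
        gene_id = sprintf("g%02d", t), transcript_id = id))
    }
    rows
  }) |> dplyr::bind_rows()
}

`%||%` <- rlang::`%||%`

is_base_allele_test <- function(a) !grepl("^[+-]", a)
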