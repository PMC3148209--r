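# Seeded simulators: aligned reads with planted variants, trio genotypes with
# injected Mendelian inconsistencies, and expression matrices with
# genotype-confounded treatment effects. Every generator is a pure function
# of its configuration (same config, byte-identical output).

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated under:
#' 80 bp single-end reads (Illumina GAIIx era) at 50-fold depth on a 10 kb
#' reference with a 0.5% base-error rate; trios of 8000 ascertained child
#' variants with a 1.5% injected Mendelian-inconsistency rate and 2% of cells
#' failing genotyping QC; expression studies of 200 genes over 20 samples
#' with effects expressed in units of the noise standard deviation.
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param reference_length,read_length,depth,base_error_rate Read-simulation
#'   parameters.
#' @param variants Tibble of planted variants: `pos` (0-based), `ref` (`NA`
#'   to keep the simulated base), `alt` (base, `"+SEQ"` or `"-L"`),
#'   `allele_fraction`, `strand_bias` (probability that an alt-carrying read
#'   is on the plus strand; 0.5 = balanced).
#' @param trio List: `n_sites`, `maf_range` (uniform bounds of the minor
#'   allele frequency), `mendelian_error_rate`, `qc_rate`, `ascertain`
#'   (keep only sites where the child carries a mutation; default `TRUE`).
#' @param expr List: `n_genes`, `n_samples`, `treatment_effect`,
#'   `genotype_effect`, `confounding_rho`, `noise_sd`, `m_snps`, `maf`;
#'   effect and rho entries may be per-gene vectors (recycled).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       reference_length = 10000L,
                       read_length = 80L,
                       depth = 50,
                       base_error_rate = 0.005,
                       variants = tibble(pos = integer(), ref = character(),
                                         alt = character(),
                                         allele_fraction = double(),
                                         strand_bias = double()),
                       trio = list(),
                       expr = list()) {
  trio <- utils::modifyList(list(n_sites = 8000L, maf_range = c(0.1, 0.5),
                                 mendelian_error_rate = 0.015, qc_rate = 0.02,
                                 ascertain = TRUE),
                            trio)
  expr <- utils::modifyList(list(n_genes = 200L, n_samples = 20L,
                                 treatment_effect = 2, genotype_effect = 1.5,
                                 confounding_rho = 0, noise_sd = 1,
                                 m_snps = 1L, maf = 0.3),
                            expr)
  probs <- c(base_error_rate, variants$allele_fraction,
             trio$mendelian_error_rate, trio$qc_rate, expr$confounding_rho)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (depth <= 0) abort("depth must be > 0")
  structure(list(seed = as.integer(seed),
                 reference_length = as.integer(reference_length),
                 read_length = as.integer(read_length), depth = depth,
                 base_error_rate = base_error_rate, variants = variants,
                 trio = trio, expr = expr),
            class = "sim_config")
}

#' Simulate aligned reads with planted variants
#'
#' Reads tile the reference at the configured depth with uniform random
#' starts. At each planted variant, covering reads carry the alternate allele
#' with the configured allele fraction, and carriers land on the plus strand
#' with probability `strand_bias`. Sequencing errors are substituted at the
#' base-error rate with low Phred scores (3-12) so quality masking can remove
#' them; correct bases get Phred 30-40. Alignments are emitted
#' coordinate-sorted with correct CIGAR strings.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, `ref.fa` and `reads.sam` are
#'   written there and their paths returned.
#' @return List with `reference` (named character vector), `reads` (a read
#'   tibble as from [read_sam()]), `truth` (the planted-variant table) and,
#'   with `dir`, `ref_path` / `sam_path`.
#' @export
sim_reads <- function(cfg, dir = NULL) {
  vs <- cfg$variants
  L <- cfg$reference_length; rl <- cfg$read_length
  if (nrow(vs) > 0 && any(vs$pos < 0 | vs$pos >= L)) {
    abort("planted variant position outside the reference")
  }
  check_indel_spacing(vs, rl, L)
  out <- withr::with_seed(cfg$seed, sim_reads_impl(cfg))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$ref_path <- file.path(dir, "ref.fa")
    out$sam_path <- file.path(dir, "reads.sam")
    write_fasta(out$reference, out$ref_path)
    write_sam(out$reads, nchar(out$reference), out$sam_path)
  }
  out
}

check_indel_spacing <- function(vs, read_length, L) {
  if (nrow(vs) == 0) return(invisible(TRUE))
  idx <- which(is_indel_allele(vs$alt))
  if (length(idx) > 1 && min(diff(sort(vs$pos[idx]))) < read_length) {
    abort("planted indels overlap within a read length; space them apart")
  }
  del <- idx[is_deletion_allele(vs$alt[idx])]
  if (length(del) > 0) {
    len <- as.integer(sub("^-", "", vs$alt[del]))
    if (any(vs$pos[del] + len > L)) abort("planted deletion runs off the reference")
  }
  invisible(TRUE)
}

sim_reads_impl <- function(cfg) {
  L <- cfg$reference_length; rl <- cfg$read_length
  reference <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  vs <- cfg$variants
  if (nrow(vs) > 0) {
    fix <- !is.na(vs$ref)
    for (i in which(fix)) substr(reference, vs$pos[i] + 1, vs$pos[i] + 1) <- vs$ref[i]
    if (any(!fix)) {
      vs$ref[!fix] <- substring(reference, vs$pos[!fix] + 1, vs$pos[!fix] + 1)
    }
    # ref SNVs equal to alt would be unobservable
    clash <- is_base_allele(vs$alt) & vs$ref == vs$alt
    if (any(clash)) abort("planted SNV alt equals the reference base")
  }
  n_reads <- max(1L, round(cfg$depth * L / rl))
  starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  carrier <- matrix(FALSE, n_reads, max(1, nrow(vs)))
  if (nrow(vs) > 0) {
    for (v in seq_len(nrow(vs))) {
      eligible <- eligible_reads(starts, rl, vs$pos[v], vs$alt[v], L)
      is_carrier <- eligible & (runif(n_reads) < vs$allele_fraction[v])
      carrier[, v] <- is_carrier
      flip <- which(is_carrier)
      strand[flip] <- ifelse(runif(length(flip)) < vs$strand_bias[v], "+", "-")
    }
  }
  reads <- purrr::map(seq_len(n_reads), function(i) {
    build_read(i, starts[i], strand[i], reference, rl, vs, carrier[i, ],
               cfg$base_error_rate)
  }) |> bind_rows()
  truth <- vs
  list(reference = c(chr1 = reference), reads = reads, truth = truth)
}

eligible_reads <- function(starts, rl, pos, alt, L) {
  if (is_base_allele(alt)) {
    starts <= pos & pos < starts + rl
  } else if (startsWith(alt, "+")) {
    ins_len <- nchar(alt) - 1L
    starts <= pos & (pos - starts + 1L + ins_len) <= rl - 1L
  } else {
    del_len <- as.integer(sub("^-", "", alt))
    starts < pos & pos < starts + rl & (starts + rl + del_len) <= L
  }
}

build_read <- function(i, start, strand, reference, rl, vs, carries, error_rate) {
  cigar <- paste0(rl, "M")
  seq <- substring(reference, start + 1L, start + rl)
  vidx <- which(carries)
  indel <- vidx[is_indel_allele(vs$alt[vidx])]
  if (length(indel) >= 1) {
    v <- indel[1]
    off <- vs$pos[v] - start              # 0-based offset of variant in read
    if (startsWith(vs$alt[v], "+")) {
      ins <- substring(vs$alt[v], 2)
      a <- off + 1L
      b <- nchar(ins)
      c_ <- rl - a - b
      seq <- paste0(substr(seq, 1, a), ins,
                    substring(reference, start + a + 1L, start + a + c_))
      cigar <- sprintf("%dM%dI%dM", a, b, c_)
    } else {
      dl <- as.integer(sub("^-", "", vs$alt[v]))
      a <- off
      b <- rl - a
      seq <- paste0(substr(seq, 1, a),
                    substring(reference, start + a + dl + 1L, start + a + dl + b))
      cigar <- sprintf("%dM%dD%dM", a, dl, b)
    }
  }
  for (v in setdiff(vidx, indel)) {
    if (length(indel) >= 1) next        # one planted event per read
    off <- vs$pos[v] - start
    substr(seq, off + 1L, off + 1L) <- vs$alt[v]
  }
  quals <- sample(30:40, rl, replace = TRUE)
  errs <- which(runif(rl) < error_rate)
  if (length(errs) > 0) {
    for (k in errs) {
      cur <- substr(seq, k, k)
      substr(seq, k, k) <- sample(setdiff(BASES, cur), 1)
    }
    quals[errs] <- sample(3:12, length(errs), replace = TRUE)
  }
  tibble(qname = sprintf("read%06d", i),
         flag = if (strand == "-") 16L else 0L,
         chrom = "chr1", pos = start,
         mapq = sample(30:60, 1), cigar = cigar, seq = seq,
         qual = int_to_phred(quals), strand = strand)
}

#' Write a read tibble as a text SAM file
#'
#' @param reads Read tibble (`qname`, `flag`, `chrom`, `pos` 0-based, `mapq`,
#'   `cigar`, `seq`, `qual`).
#' @param chrom_lengths Named lengths for the `@SQ` header lines.
#' @param path Output path.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos + 1L,
                  reads$mapq, reads$cigar, reads$seq,
                  ifelse(is.na(reads$qual), "*", reads$qual))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

# Biallelic trio machinery (independent of the cohort module): categories as
# allele counts 0/1/2 of the alternate allele.
.trio_cats <- c("hom_ref", "het_mut", "hom_mut")

trio_is_consistent <- function(f, m, c) {
  fa <- list(c(0, 0), c(0, 1), c(1, 1))[[f]]
  ma <- list(c(0, 0), c(0, 1), c(1, 1))[[m]]
  ch <- sort(list(c(0, 0), c(0, 1), c(1, 1))[[c]])
  for (x in unique(fa)) for (y in unique(ma)) {
    if (identical(sort(c(x, y)), ch)) return(TRUE)
  }
  FALSE
}

#' Simulate a trio genotype set with injected Mendelian inconsistencies
#'
#' Sites are ascertained on the child carrying a mutation (a child variant
#' list): parental genotypes are drawn from Hardy-Weinberg proportions at a
#' minor allele frequency uniform over `maf_range`, the child by Mendelian
#' transmission, and sites with a non-mutated child are redrawn. With
#' probability `mendelian_error_rate` a site is replaced by a trio drawn
#' uniformly from the inconsistent genotype triples with a mutated child, so
#' the injected rate is exactly the expected per-child Mendelian error rate
#' over the ascertained sites. Each resulting cell is independently set to
#' `qc` with probability `qc_rate`. With `ascertain = FALSE` sites are kept
#' regardless of the child's genotype (pure transmission draws).
#'
#' @param cfg A [sim_config()]; see the `trio` element.
#' @return List with `calls` (named list of father/mother/child call tibbles
#'   usable by [aggregate_genotypes()]) and `truth` (per-site pre-QC
#'   categories and the `is_error` labels).
#' @export
sim_trio <- function(cfg) {
  withr::with_seed(cfg$seed + 1L, sim_trio_impl(cfg$trio))
}

sim_trio_impl <- function(ts) {
  n <- ts$n_sites
  draw <- function(n_draw) {
    q <- runif(n_draw, ts$maf_range[1], ts$maf_range[2])
    f <- rbinom(n_draw, 2, q) + 1L       # 1..3 indexes .trio_cats
    m <- rbinom(n_draw, 2, q) + 1L
    # transmission: one allele from each parent, P(alt) = alt-allele dosage / 2
    fa <- rbinom(n_draw, 1, (f - 1) / 2)
    ma <- rbinom(n_draw, 1, (m - 1) / 2)
    tibble(f = f, m = m, c = fa + ma + 1L)
  }
  if (ts$ascertain) {
    sites <- tibble(f = integer(), m = integer(), c = integer())
    tries <- 0L
    while (nrow(sites) < n) {
      batch <- draw(2L * (n - nrow(sites)) + 10L)
      sites <- bind_rows(sites, filter(batch, .data$c > 1L))
      tries <- tries + 1L
      if (tries > 1000L) {
        abort("cannot ascertain mutated children; raise maf_range or set trio$ascertain = FALSE")
      }
    }
    sites <- sites[seq_len(n), ]
  } else {
    sites <- draw(n)
  }
  # all inconsistent triples with a mutated child
  grid <- tidyr::crossing(f = 1:3, m = 1:3, c = 2:3) |>
    filter(!purrr::pmap_lgl(list(.data$f, .data$m, .data$c), trio_is_consistent))
  is_error <- runif(n) < ts$mendelian_error_rate
  if (any(is_error)) {
    repl <- grid[sample.int(nrow(grid), sum(is_error), replace = TRUE), ]
    sites[is_error, ] <- repl
  }
  truth <- tibble(chrom = "chr1", pos = seq_len(n) - 1L, ref = "A", alt = "G",
                  father = .trio_cats[sites$f], mother = .trio_cats[sites$m],
                  child = .trio_cats[sites$c], is_error = is_error)
  calls <- purrr::map(c(father = "father", mother = "mother", child = "child"),
    function(role) {
      g <- truth[[role]]
      g[runif(n) < ts$qc_rate] <- "qc"
      tibble(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
             alt = truth$alt, genotype = g)
    })
  list(calls = calls, truth = truth)
}

#' Simulate an expression study with genotype-confounded treatment effects
#'
#' Expression follows the additive model `e = b0 + b * tr + sum_j b_j * SNP_j
#' + noise` with Gaussian noise on the (log-scale) expression values. Each
#' sample's SNP code is tied to its treatment group with probability
#' `confounding_rho` (0 with control, 2 with treatment) and otherwise drawn
#' binomially at the configured allele frequency, so `rho = 1` reproduces
#' complete treatment-genotype confounding and `rho = 0` independence.
#'
#' @param cfg A [sim_config()]; see the `expr` element, whose
#'   `treatment_effect`, `genotype_effect` and `confounding_rho` entries may
#'   be per-gene vectors.
#' @return List with `expression` (wide tibble, `feature_id` + samples),
#'   `design` (`sample`, `treatment`), `genotypes` (`snp_id` + samples, codes
#'   0/1/2), `gene_snps` (`feature_id`, `snp_id`), `gene_loci`, `snp_loci`
#'   and `truth` (per-gene true coefficients).
#' @export
sim_expression <- function(cfg) {
  withr::with_seed(cfg$seed + 2L, sim_expression_impl(cfg$expr))
}

sim_expression_impl <- function(es) {
  n <- es$n_samples
  if (n < 6) abort("n_samples must be >= 6")
  g <- es$n_genes
  b_tr <- rep_len(es$treatment_effect, g)
  b_snp <- rep_len(es$genotype_effect, g)
  rho <- rep_len(es$confounding_rho, g)
  m <- es$m_snps
  samples <- sprintf("S%02d", seq_len(n))
  treated <- c(rep(0L, floor(n / 2)), rep(1L, ceiling(n / 2)))
  design <- tibble(sample = samples,
                   treatment = ifelse(treated == 1, "treated", "control"))
  expr_rows <- vector("list", g)
  geno_rows <- vector("list", g)
  maps <- vector("list", g)
  truth <- vector("list", g)
  for (k in seq_len(g)) {
    snp_ids <- sprintf("gene%03d_snp%d", k, seq_len(m))
    codes <- matrix(NA_real_, nrow = m, ncol = n)
    for (j in seq_len(m)) {
      confounded <- runif(n) < rho[k]
      codes[j, ] <- ifelse(confounded, 2 * treated, rbinom(n, 2, es$maf))
    }
    e <- 5 + b_tr[k] * treated + colSums(codes * b_snp[k]) +
      rnorm(n, 0, es$noise_sd)
    expr_rows[[k]] <- tibble(feature_id = sprintf("gene%03d", k),
                             !!!setNames(as.list(e), samples))
    geno_rows[[k]] <- tibble(snp_id = snp_ids) |>
      bind_cols(as_tibble(codes, .name_repair = ~samples))
    maps[[k]] <- tibble(feature_id = sprintf("gene%03d", k), snp_id = snp_ids)
    truth[[k]] <- tibble(feature_id = sprintf("gene%03d", k),
                         treatment_effect = b_tr[k], genotype_effect = b_snp[k],
                         confounding_rho = rho[k])
  }
  gene_loci <- tibble(feature_id = sprintf("gene%03d", seq_len(g)),
                      chrom = "chr1", start = seq_len(g) * 10000L,
                      end = seq_len(g) * 10000L + 5000L)
  snp_loci <- bind_rows(maps) |>
    left_join(gene_loci, by = "feature_id") |>
    mutate(pos = .data$start + 100L) |>
    select("snp_id", "chrom", "pos")
  list(expression = bind_rows(expr_rows), design = design,
       genotypes = bind_rows(geno_rows), gene_snps = bind_rows(maps),
       gene_loci = gene_loci, snp_loci = snp_loci, truth = bind_rows(truth))
}
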