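# Four-criterion filter, genotype categories, ASE and call annotation.

test_that("a clean heterozygous site passes all four criteria", {
  col <- make_col("A", list(
    A = list(plus = 8, minus = 7),
    G = list(plus = 5, minus = 5)))
  fs <- filter_site(col, filter_config())
  expect_true(fs$pass)
  expect_length(fs$reasons, 0)
  expect_equal(fs$alt, "G")
  expect_equal(fs$alt_count, 10L)
  expect_equal(fs$alt_freq, 0.4)
})

test_that("depth below the coverage threshold fails with reason coverage", {
  col <- make_col("A", list(
    A = list(plus = 7, minus = 7),
    G = list(plus = 3, minus = 2)))   # depth 19
  fs <- filter_site(col, filter_config())
  expect_false(fs$pass)
  expect_equal(fs$reasons, "coverage")
})

test_that("strand-imbalanced alt support fails the strand criterion", {
  col <- make_col("A", list(
    A = list(plus = 9, minus = 9),
    G = list(plus = 11, minus = 1)))  # minor strand 1/12 < 0.1
  fs <- filter_site(col, filter_config())
  expect_false(fs$pass)
  expect_equal(fs$reasons, "strand")
})

test_that("low-quality bases are removed from the coverage before filtering", {
  col <- make_col("A", list(
    A = list(plus = 12, minus = 12,
             quals_plus = c(rep(30L, 8), rep(5L, 4)),
             quals_minus = rep(30L, 12)),
    G = list(plus = 5, minus = 5,
             quals_plus = rep(30L, 5), quals_minus = rep(30L, 5))))
  fs <- filter_site(col, filter_config())
  expect_equal(fs$effective_depth, 30L)   # 4 masked bases gone
  expect_equal(fs$alt_freq, 10 / 30)
  # with masking disabled the same site has depth 34
  fs0 <- filter_site(col, filter_config(min_base_qual = 0))
  expect_equal(fs0$effective_depth, 34L)
})

test_that("quality masking is idempotent and a zero threshold is the identity", {
  withr::local_seed(31)
  for (i in 1:20) {
    col <- random_column()
    m1 <- mask_quality(col, 10)
    m2 <- mask_quality(m1, 10)
    expect_equal(as.data.frame(m1), as.data.frame(m2))
    m0 <- mask_quality(col, 0)
    expect_equal(as.data.frame(m0),
                 as.data.frame(col[col$plus + col$minus > 0, ]))
  }
})

test_that("filter decisions match the independent four-criterion checker", {
  withr::local_seed(41)
  n_checked <- 0
  for (i in 1:1000) {
    col <- random_column()
    fs <- filter_site(col, filter_config())
    oracle <- oracle_filter(col)
    expect_identical(fs$pass, oracle$pass)
    expect_setequal(fs$reasons, oracle$reasons)
    if (oracle$candidate) {
      expect_identical(fs$alt, oracle$alt)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 500)
})

test_that("raising any threshold never converts a failing site into a passing one", {
  withr::local_seed(51)
  base <- filter_config()
  # the three decision thresholds; the base-quality mask is excluded because
  # it reshapes the evidence (dropping low-quality reference bases can raise
  # the alt fraction) rather than tightening a criterion
  stricter <- list(
    filter_config(min_coverage = 30),
    filter_config(min_minor_strand_freq = 0.3),
    filter_config(min_alt_freq = 0.4))
  for (i in 1:200) {
    col <- random_column()
    fs <- filter_site(col, base)
    for (cfg in stricter) {
      if (!fs$pass) expect_false(filter_site(col, cfg)$pass)
    }
  }
})

test_that("genotype categories follow the zygosity boundary and coverage rule", {
  hom <- make_col("A", list(A = list(plus = 1, minus = 0),
                            G = list(plus = 10, minus = 9)))
  expect_equal(call_genotype(hom, filter_config()), "hom_mut")   # freq 0.95
  het <- make_col("A", list(A = list(plus = 9, minus = 9),
                            G = list(plus = 6, minus = 6)))
  expect_equal(call_genotype(het, filter_config()), "het_mut")   # freq 0.40
  # non-mutated positions: category depends on the coverage threshold alone
  shallow <- make_col("A", list(A = list(plus = 4, minus = 4)))
  expect_equal(call_genotype(shallow, filter_config()), "qc")    # depth 8
  deep <- make_col("A", list(A = list(plus = 15, minus = 10)))
  expect_equal(call_genotype(deep, filter_config()), "hom_ref")
  # failing candidate
  bad <- make_col("A", list(A = list(plus = 8, minus = 8),
                            G = list(plus = 2, minus = 1)))
  expect_equal(call_genotype(bad, filter_config()), "qc")
})

test_that("with hom_alt_freq = 1 only pure-alt sites are called homozygous", {
  cfg <- filter_config(hom_alt_freq = 1)
  pure <- make_col("A", list(G = list(plus = 15, minus = 15)))
  expect_equal(call_genotype(pure, cfg), "hom_mut")
  near <- make_col("A", list(A = list(plus = 1, minus = 0),
                             G = list(plus = 15, minus = 15)))
  expect_equal(call_genotype(near, cfg), "het_mut")
})

test_that("call_variants records ASE counts and filter reasons per site", {
  pu <- dplyr::bind_rows(
    make_col("A", list(A = list(plus = 6, minus = 6),
                       T = list(plus = 4, minus = 4)), pos = 10L),
    make_col("C", list(C = list(plus = 3, minus = 2)), pos = 20L))
  class(pu) <- c("seqmine_pileup", class(pu))
  calls <- call_variants(pu, filter_config())
  expect_equal(nrow(calls), 1)          # pos 20 has no alternate evidence
  expect_equal(calls$pos, 10L)
  expect_equal(calls$ase[[1]], c(A = 12L, T = 8L))
  expect_equal(calls$genotype, "het_mut")
})

test_that("annotation attaches known ids, transcripts and consequences", {
  # reference with a CDS covering positions 100..129 (0-based), strand +
  ref <- c(chr1 = paste0(strrep("A", 100), "ATGGTGTGGCCCACGTTTGGGAAACCCTAG",
                         strrep("A", 100)))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr1", type = c("exon", "CDS"), start = 101L, end = 130L,
    strand = "+", gene_id = "g1", transcript_id = c("t1", "t1")))
  idx <- load_gene_models(gtf)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t105\trs9\tT\tA\t.\t.\t.",
               "chr1\t50\trs8\tA\tC\t.\t.\t.",
               "chr1\t200\trs7\tG\tC\t.\t.\t."), vcf)
  known <- read_known_sites(vcf)
  calls <- tibble::tibble(
    chrom = "chr1", pos = 104L, ref = "T", alt = "A",
    effective_depth = 40L, alt_count = 18L, alt_plus = 9L, alt_minus = 9L,
    alt_freq = 0.45, pass = TRUE, genotype = "het_mut",
    filter_reasons = list(character(0)), ase = list(c(T = 22L, A = 18L)))
  ann <- annotate_calls(calls, idx, known_sites = known, reference = ref)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$known_id, "rs9")
  expect_equal(ann$region_category, "exon_coding")
  # codon 2 GTG -> GAG is Val -> Glu
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$amino_acid_change, "Val->Glu")
  expect_equal(ann$codon_number, 2L)
  expect_equal(ann$ase[[1]], c(T = 22L, A = 18L))
})

test_that("a call overlapping three transcripts is annotated three times", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr2", type = "exon", start = 1001L, end = 1500L, strand = "+",
    gene_id = "gA", transcript_id = c("nm1", "nm2", "nm3")))
  idx <- load_gene_models(gtf)
  calls <- tibble::tibble(
    chrom = "chr2", pos = 1200L, ref = "A", alt = "T",
    effective_depth = 30L, alt_count = 15L, alt_plus = 8L, alt_minus = 7L,
    alt_freq = 0.5, pass = TRUE, genotype = "het_mut",
    filter_reasons = list(character(0)), ase = list(c(A = 15L, T = 15L)))
  ann <- annotate_calls(calls, idx)
  expect_equal(nrow(ann), 3)
  expect_setequal(ann$transcript_id, c("nm1", "nm2", "nm3"))
  expect_true(all(is.na(ann$known_id)))
})

test_that("minus-strand consequences reverse-complement the alleles", {
  # minus-strand CDS: genomic positions 100..105 hold the reverse complement
  # of ATGGTG; CDS (coding order) is ATGGTG, so genomic is CACCAT
  ref <- c(chr1 = paste0(strrep("G", 100), "CACCAT", strrep("G", 100)))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr1", type = c("exon", "CDS"), start = 101L, end = 106L,
    strand = "-", gene_id = "g1", transcript_id = c("t1", "t1")))
  idx <- load_gene_models(gtf)
  # genomic A>T at pos 104 (0-based) is CDS position 1 T>A: GTG stays... use
  # pos 101 (genomic A>C is CDS T... ) -- check a missense: genomic C>A at
  # 100 is CDS position 5 G>T: GTG -> GTT still Val (synonymous)
  calls <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "C", alt = "A",
    effective_depth = 30L, alt_count = 15L, alt_plus = 8L, alt_minus = 7L,
    alt_freq = 0.5, pass = TRUE, genotype = "het_mut",
    filter_reasons = list(character(0)), ase = list(c(C = 15L, A = 15L)))
  ann <- annotate_calls(calls, idx, reference = ref)
  expect_equal(ann$consequence, "synonymous")
  expect_equal(ann$codon_number, 2L)
})
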