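# Gene-model loading, coordinate conventions, site classification and coding
# consequences.

test_that("GTF coordinates are normalized to 0-based half-open", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr1", type = "exon", start = c(100L, 300L), end = c(200L, 400L),
    strand = "+", gene_id = "g1", transcript_id = "t1"))
  idx <- load_gene_models(gtf)
  ex <- idx$exons
  expect_equal(ex$start, c(99L, 299L))
  expect_equal(ex$end, c(200L, 400L))
  expect_equal(ex$end - ex$start, c(101L, 101L))
  expect_equal(idx$transcripts$tx_start, 99L)
  expect_equal(idx$transcripts$tx_end, 400L)
})

test_that("empty gene-model file loads as an empty index", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), bed)
  idx <- load_gene_models(bed)
  expect_equal(nrow(idx$transcripts), 0)
  expect_equal(nrow(classify_site(idx, "chr1", 100L)), 0)
})

test_that("BED12 blocks reproduce blockStarts/blockSizes exactly", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # blockCount = 3; independent BED12 arithmetic: exon k spans
  # [chromStart + blockStarts[k], chromStart + blockStarts[k] + blockSizes[k])
  chrom_start <- 1000L
  block_sizes <- c(120L, 80L, 200L)
  block_starts <- c(0L, 400L, 900L)
  writeLines(sprintf("chr2\t%d\t%d\ttxA\t0\t-\t%d\t%d\t0\t3\t%s\t%s",
                     chrom_start, chrom_start + 1100L, chrom_start + 10L,
                     chrom_start + 1090L,
                     paste(block_sizes, collapse = ","),
                     paste(block_starts, collapse = ",")), bed)
  idx <- load_gene_models(bed)
  expect_equal(idx$exons$start, chrom_start + block_starts)
  expect_equal(idx$exons$end, chrom_start + block_starts + block_sizes)
  expect_equal(idx$transcripts$strand, "-")
})

test_that("malformed gene-model lines are reported with their line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
               "chr1\tsrc\texon\tnot_a_number"), gtf)
  expect_error(load_gene_models(gtf), "line 2")
})

test_that("BED12 round trip through write_bed12 preserves exon structures", {
  withr::local_seed(11)
  for (rep in 1:5) {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    write_test_gtf(gtf, random_annotation_rows(n_tx = 6))
    idx <- load_gene_models(gtf)
    bed <- withr::local_tempfile(fileext = ".bed")
    write_bed12(idx, bed)
    idx2 <- load_gene_models(bed)
    ex1 <- dplyr::arrange(idx$exons, transcript_id, start)
    ex2 <- dplyr::arrange(idx2$exons, transcript_id, start)
    expect_equal(ex1[c("transcript_id", "chrom", "strand", "start", "end")],
                 ex2[c("transcript_id", "chrom", "strand", "start", "end")])
    tx1 <- dplyr::arrange(idx$transcripts, transcript_id)
    tx2 <- dplyr::arrange(idx2$transcripts, transcript_id)
    expect_equal(tx1$cds_start, tx2$cds_start)
    expect_equal(tx1$cds_end, tx2$cds_end)
  }
})

test_that("classify_site agrees with a brute-force scan over all transcripts", {
  withr::local_seed(7)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, random_annotation_rows(n_tx = 10))
  flank <- 500L
  idx <- load_gene_models(gtf, flank_size = flank)
  tx <- idx$transcripts
  for (pos in sample(0:50000, 1000)) {
    got <- classify_site(idx, "chr1", pos)
    covering <- tx$transcript_id[tx$tx_start - flank <= pos &
                                 pos < tx$tx_end + flank]
    expect_setequal(got$transcript_id, covering)
  }
})

test_that("UTR and coding assignments are mutually exclusive within a CDS transcript", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr1", type = c("exon", "exon", "CDS"),
    start = c(101L, 301L, 151L), end = c(200L, 400L, 350L),
    strand = "+", gene_id = "g1", transcript_id = "t1"))
  idx <- load_gene_models(gtf)
  exonic <- c(100:199, 300:399)
  for (pos in exonic) {
    region <- classify_site(idx, "chr1", pos)$region_category
    expect_length(region, 1)
    expect_true(region %in% c("5'UTR", "3'UTR", "exon_coding"))
  }
  expect_equal(classify_site(idx, "chr1", 120L)$region_category, "5'UTR")
  expect_equal(classify_site(idx, "chr1", 160L)$region_category, "exon_coding")
  expect_equal(classify_site(idx, "chr1", 380L)$region_category, "3'UTR")
})

test_that("splice sites are the first and last two intronic bases", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr1", type = "exon", start = c(101L, 301L), end = c(200L, 400L),
    strand = "+", gene_id = "g1", transcript_id = "t1"))
  idx <- load_gene_models(gtf)
  # intron is [200, 300) internally
  expect_equal(classify_site(idx, "chr1", 200L)$region_category, "splice_site")
  expect_equal(classify_site(idx, "chr1", 201L)$region_category, "splice_site")
  expect_equal(classify_site(idx, "chr1", 202L)$region_category, "intron")
  expect_equal(classify_site(idx, "chr1", 297L)$region_category, "intron")
  expect_equal(classify_site(idx, "chr1", 298L)$region_category, "splice_site")
  expect_equal(classify_site(idx, "chr1", 299L)$region_category, "splice_site")
})

test_that("positions overlapping several transcripts yield one record each", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, tibble::tibble(
    chrom = "chr2", type = "exon", start = 1001L, end = 2000L, strand = "+",
    gene_id = "gA", transcript_id = c("tx1", "tx2", "tx3")))
  idx <- load_gene_models(gtf)
  got <- classify_site(idx, "chr2", 1500L)
  expect_equal(nrow(got), 3)
  expect_setequal(got$transcript_id, c("tx1", "tx2", "tx3"))
})

test_that("coding consequences follow the genetic code and frame arithmetic", {
  # GTG -> GAG : Val -> Glu
  got <- coding_consequence("GTGTGG", 1L, "T", "A")
  expect_equal(got$consequence, "missense")
  expect_equal(got$amino_acid_change, "Val->Glu")
  expect_equal(got$codon_number, 1L)
  # TGG -> TGA : nonsense
  got <- coding_consequence("GTGTGG", 5L, "G", "A")
  expect_equal(got$consequence, "nonsense")
  # 2-base deletion: frameshift; 3-base: in-frame
  expect_equal(coding_consequence("GTGTGG", 2L, "G", "-2")$consequence, "frameshift")
  expect_equal(coding_consequence("GTGTGG", 2L, "G", "-3")$consequence, "inframe_indel")
  expect_equal(coding_consequence("GTGTGG", 2L, "G", "+A")$consequence, "frameshift")
  # synonymous third-position change: GTG -> GTA (both Val)
  expect_equal(coding_consequence("GTGTGG", 2L, "G", "A")$consequence, "synonymous")
  # codon numbering
  expect_equal(coding_consequence("GTGTGG", 3L, "T", "C")$codon_number, 2L)
  # errors
  expect_error(coding_consequence("GTGTG", 0L, "G", "A"), "divisible by 3")
  expect_error(coding_consequence("GTGTGG", 0L, "C", "A"), "mismatch")
})

test_that("known-site VCF parsing normalizes SNVs and indels", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tG\t.\t.\t.",
    "chr1\t200\trs2\tAC\tA\t.\t.\t.",
    "chr1\t300\trs3\tT\tTAG,C\t.\t.\t."), vcf)
  ks <- read_known_sites(vcf)
  expect_equal(nrow(ks), 4)
  snv <- ks[ks$known_id == "rs1", ]
  expect_equal(snv$pos, 99L)
  del <- ks[ks$known_id == "rs2", ]
  expect_equal(del$pos, 200L)     # first deleted base, 0-based
  expect_equal(del$alt, "-1")
  ins <- ks[ks$known_id == "rs3" & startsWith(ks$alt, "+"), ]
  expect_equal(ins$alt, "+AG")
  expect_equal(ins$pos, 299L)
})
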