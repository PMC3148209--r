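Package: seqmine
Title: Post-Alignment Mining of Exome and Transcriptome Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis toolkit for exome and RNA sequencing.
    Builds per-position pileups from SAM alignments, detects and filters SNPs
    and short indels with a four-criterion rule-based filter (coverage, base
    quality, strand balance, alternate-allele frequency), genotypes and
    annotates calls against gene models, aggregates genotypes across samples
    with trio Mendelian-error quality control, quantifies per-base coverage
    and RPKM expression, tests for differential expression with and without
    genotype control (linear models with SNP covariates), scans for cis and
    trans expression quantitative trait loci, scores SNP-to-gene associations
    by shortest-path distance over merged directed pathway graphs, and
    segments exon-level copy-number signals by circular binary segmentation.
    Includes seeded simulators for aligned reads with planted variants, trio
    genotypes with injected Mendelian inconsistencies, and expression data
    with genotype-confounded treatment effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
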