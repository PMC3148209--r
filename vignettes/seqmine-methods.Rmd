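---
title: "seqmine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqmine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmine)
```

seqmine mines coordinate-sorted SAM alignments from exome and RNA
sequencing: it builds per-position pileups, detects and filters SNPs and
short indels, genotypes and annotates them against gene models, aggregates
genotypes across samples with trio Mendelian-error quality control,
quantifies coverage and RPKM expression, tests differential expression with
and without genotype control, scans for eQTLs, scores SNP-gene associations
by pathway distance, and segments exon-level copy-number signals. This
vignette records the statistical models, the package's conventions, and the
design decisions a maintainer would want to know about.

## Coordinates and allele encoding

All internal coordinates are 0-based half-open. The 1-based conventions of
GTF, VCF and SAM are converted at the parsing boundary, and 1-based
coordinates reappear only in display output (pileup TSV, `.seg`, WIG). A
single arithmetic convention avoids off-by-one drift between modules.

Alleles are encoded as the alternate base for substitutions, `"+SEQ"` for an
insertion anchored after the reported position (the convention of standard
pileup formats), and `"-L"` for a deletion of `L` bases whose first deleted
base is the reported position.

## The mutation filter

A candidate site is any pileup position with alternate evidence surviving
base-quality masking. The filter applies, in order:

1. **Base-quality masking.** Base calls with Phred quality below
   `min_base_qual` (default 10) are removed from the coverage before
   anything is counted. Indel evidence carries no base quality and is never
   masked.
2. **Coverage.** Effective depth must reach `min_coverage` (default 20).
   Effective depth counts base evidence plus deletion-supporting reads:
   a read whose deletion spans the position covers it without contributing
   a base call, and excluding such reads would overstate the alternate
   fraction of deletion alleles.
3. **Minor sequenced strand frequency.** Among the alternate-supporting
   reads, the minor strand must hold at least `min_minor_strand_freq`
   (default 0.1) of the support. The strand criterion is computed on
   alt-supporting reads because supporting-read strand imbalance is the
   standard signature of a strand artifact; balance among all covering
   reads says little about the allele in question.
4. **Mutated base frequency.** The alternate fraction of the effective
   depth must reach `min_alt_freq` (default 0.25).

All comparisons are inclusive (at least), reading the published defaults as
minima. The candidate alternate allele is the highest-count non-reference
allele, with ties broken `A < C < G < T <` indels and indels among
themselves lexicographically; multi-allelic sites therefore resolve
deterministically. Indels pass through the same four criteria with the
insertion sequence or deletion length as the allele.

One subtlety worth stating: the three decision thresholds are monotone
(raising any of them can only turn passes into failures), but the
base-quality mask is not a threshold in that sense. Raising it can remove
low-quality *reference* bases, raise the alternate fraction, and turn a
failing site into a passing one. The masking step reshapes the evidence; it
does not tighten a criterion.

## Genotype categories

Candidate sites that pass the filter are `hom_mut` when the alternate
fraction is at least `hom_alt_freq` (default 0.75) and `het_mut` otherwise;
candidates that fail are `qc` (unknown genotype). Non-candidate positions
are `hom_ref` when the effective depth reaches the coverage threshold and
`qc` otherwise, so shallow reference-only positions are never asserted to
be reference homozygotes. The 0.75 boundary is a configurable package
default: a diploid heterozygote is expected near 0.5 and a homozygote near
1.0, and 0.75 is the midpoint; the literature the filter follows announces
zygosity calls without printing its boundary.

## Annotation

Gene models load from GTF or BED12 into one internal form; positions
classify per overlapping transcript as upstream/downstream (within a
configurable 1000 bp flank), 5'/3' UTR, coding exon, non-coding exon,
intron, or splice site. The splice-site window is the first and last 2
intronic bases of each intron — the canonical donor/acceptor dinucleotides —
because the source categories name splice sites without quantifying them.
Coding consequences translate codons under the standard genetic code
(synonymous, missense, nonsense; frameshift versus in-frame by indel length
modulo 3), and minus-strand transcripts reverse-complement the alleles
before codon lookup. A variant overlapping several transcripts is annotated
once per transcript, mirroring how a single mutation is reported against
every RefSeq isoform it touches.

## Trio quality control

Genotype matrices key variants by (chrom, pos, ref, alt) — allele-level keys
are stricter than position keys and lossless. Samples without a call at a
key are re-evaluated from their own pileup as `hom_ref` or `qc` by the
coverage rule. The family-wise filter removes every row where any trio
member is `qc`. Mendelian consistency maps the categories to biallelic
genotypes (RR/RA/AA) and asks whether the child's pair can be drawn one
allele from each parent. Per-sample error rates use as denominator the rows
where that sample is mutated, matching per-individual SNP accounting in
trio studies, with `rate = failed / (passed + failed)`.

## Coverage and expression

Coverage depth at a base counts reads whose aligned CIGAR span (M/=/X/D)
covers it; deletions count as covered (an exome deletion is still locally
sequenced) while N skips do not (an RNA splice gap is not). WIG output is
fixedStep, step 1, one block per chromosome, chosen so the write/read round
trip is exact.

Exome QC reports `mde` (mean of per-exon average coverage), `ec5`/`ec10`
(percent of exons with average coverage of at least 5/10 fold; inclusive
thresholds, consistent with the variant filter), coverage specificity
(percent of mapped reads on target exons) and the quantiles of per-exon
average coverage.

Expression is quantified as RPKM: `count / (exon-model kb) / (millions of
mapped reads)`, where mapped reads are those passing the mapping-quality
filter in the sample, not the library size. A read counts once for every
transcript (or exon) whose exon union it overlaps; no multi-mapping rescue
or fractional apportionment is attempted. Exon-level features count a read
once per overlapped exon.

## Differential expression and genotype control

For two groups the per-feature report is the log2 fold change of group
means with a 0.5 pseudocount (tolerating zeros), the equal-variance
Student's t-test, the Wilcoxon rank-sum test, and Benjamini–Hochberg FDR
over the t-test p-values.

The genotype-controlled procedure fits, per gene with expression $e$ over
$n$ samples:

$$e_i = \beta_0 + \beta\,tr_i + \varepsilon_i \qquad \text{(uncontrolled)}$$

$$e_i = \beta_0 + \sum_{j=1}^{m} \beta_j\,SNP_{ij} + \beta'\,tr_i +
\varepsilon_i \qquad \text{(controlled)}$$

with $tr$ the two-level treatment and $SNP_{ij} \in \{0,1,2\}$ the additive
code of the $j$-th SNP inside the gene ($n \ge m + 3$ is required). The
uncontrolled slope test is numerically identical to the pooled-variance
two-sample t-test, which the test suite verifies to $10^{-10}$. A gene is a
genotype-controlled DEG when **both** slope tests are significant (default
$\alpha = 0.01$ for each). The controlled model is a fixed-effects `lm` fit
— the model is stated in fixed-effects notation, and a mixed-effects
machinery would add estimation choices without changing the tested
contrast. When the genotype covariates perfectly alias the treatment
(complete confounding), the treatment coefficient is inestimable and the
adjusted p-value is reported as 1.0 rather than an error: confounded genes
are silently non-significant after control, which is the behaviour the
procedure exists to produce. Genotype coding is additive because the
source never states its coding and additivity is the standard single-SNP
default.

Variance components are the sequential (type-I) sum-of-squares
decomposition of the controlled fit in the order genotype block, then
treatment, then residual, normalized by the total sum of squares. A
sequential decomposition is a declared stand-in for the original
mixed-model variance components, whose exact specification (which factors
random, which estimation method) is not recoverable; the decomposition is
validated qualitatively — controlled selections show lower residual and
higher genotype fractions than naive ones on synthetic mixtures.

## eQTL scanning

Each (gene, SNP) pair is a simple linear regression of expression on the
additive genotype code; `qc`/missing codes are excluded pairwise,
monomorphic SNPs are skipped, and Bonferroni adjustment multiplies by the
number of tests actually performed in the scan. A pair is *cis* when the
SNP lies within the gene span extended by 1 Mb (configurable) on each side
and *trans* otherwise; the 1 Mb window is the common eQTL convention, since
the only definition in the source (same gene) is too narrow for a scan.

## Pathway-distance association

All pathway graphs merge into one directed graph with unit edge weights;
`d[i, j]` is the shortest directed path length, with unreachable pairs set
to $N$ (the gene count) and the diagonal 0. The p-value of an ordered
(gSNP, gDEG) pair is

$$p = \frac{\#\{(i,j) : d_{ij} \le d_{gSNP,\,gDEG}\}}{N^2},$$

counting all ordered pairs including the diagonal. The $N^2$ background
(rather than $N^2 - N$) makes the cis case — distance 0 — well-defined and
non-zero, and the `<=` indicator is the conservative tie treatment for a
left-tail distance statistic; both choices are isolated behind this one
formula. Cis pairs are therefore always minimal, and the p-value is
monotone in distance. Shortest paths are computed by igraph; the test suite
holds them to an independent breadth-first-search oracle, exactly, on
random digraphs.

## Copy-number segmentation

Probe signals are per-exon `log2((sample RPKM + 0.5) / (reference RPKM +
0.5))` against a normal sample or a pool averaged on the RPKM scale; the
pseudocount keeps zero-RPKM exons finite. The log-ratio (rather than the
raw log RPKM) is used because a reference is what turns exon coverage into
a copy-number signal. Only exon probes are emitted — intronic and
intergenic calls from capture data are not trustworthy.

Segmentation is circular binary segmentation implemented directly: on a
segment of $k$ probes every arc $(i, j]$ is scored by
$Z = (\bar{x}_{arc} - \bar{x}_{comp}) / \sqrt{1/n_1 + 1/n_2}$, the arc
maximizing $|Z|$ is the candidate, and the split is accepted when the
permutation p-value $(1 + \#\{exceedances\})/(1 + n_{perm})$ falls below
`alpha` (default 0.01, 1000 permutations). Permutation scanning stops early
once the exceedance count makes $p \ge \alpha$ certain, which is what makes
null segments cheap. Accepted splits recurse into the resulting pieces.
The mean-difference statistic is rank-equivalent to the classical t form
under permutation of the segment's own values; the published pruning and
undo refinements are omitted as a declared simplification adequate at
exon-probe scale. Segments report the arithmetic mean of member probes, and
`.seg` output is 1-based inclusive with means at 4 decimals for genome
viewers.

## The simulators

The generators exist so the full pipeline is testable without downloads,
and their defaults are the validation conditions: 80 bp reads (the
paired-end read length of the GAIIx era) at 50-fold depth — within the
44–117-fold range reported for exome captures — over a 10 kb reference with
a 0.5% base-error rate; trios of 8000 child-variant sites with a 1.5%
injected inconsistency rate and 2% of cells failing genotyping QC; and
expression studies of 200 genes over 20 samples with effects in units of
the noise standard deviation.

`sim_reads` writes coordinate-sorted SAM with correct CIGARs directly —
alignment itself is out of scope, so the aligner's *output* is the correct
fixture boundary. Carrier reads are Bernoulli draws at the planted allele
fraction, carrier strand is Bernoulli at the planted strand bias, and
sequencing errors get Phred 3–12 (maskable) against 30–40 elsewhere. It
does not model platform error profiles, PCR duplicates, paired-end
structure, or splicing.

`sim_trio` emulates a child variant list: parents are Hardy–Weinberg draws
at a uniform minor allele frequency, children follow Mendelian
transmission, and sites are ascertained on a mutated child. An error site
redraws the whole trio uniformly from the inconsistent triples with a
mutated child. This design makes the injected rate exactly the expectation
of the per-child error-rate estimator (whose denominator is child-mutated
rows); injecting by corrupting the child genotype unconditionally would
bias the estimator upward by roughly the reciprocal of the child-mutation
fraction, and for het × het parents no inconsistent genotype even exists.
With `ascertain = FALSE` the generator returns pure transmission draws.

`sim_expression` generates the additive model above with Gaussian noise on
log-scale expression (the linear models assume additive errors). The
confounding knob ties each sample's SNP code to its treatment group with
probability `rho` (code 2 under treatment, 0 under control) and draws it
binomially at the configured allele frequency otherwise, so `rho = 1`
reproduces complete confounding — the treated samples carrying one genotype
and the controls another — and `rho = 0` independence.

What passing tests on these generators shows is that the *methods* behave
as specified under their own model assumptions; it does not certify
performance on real data, where alignment artifacts, capture bias,
overdispersed counts and linkage structure all violate the generators'
independence assumptions.

## Validation problem sizes

The test suite validates the filter against an independently coded
four-criterion checker on 10,000 random pileup columns; trio verdicts
against exhaustive transmission enumeration on all 27 category triples; the
injected 1.5% trio error rate over 8000 sites within its 95% binomial
interval; RPKM against its closed form to 1e-12; the slope/t-test
equivalence on 1000 random datasets to 1e-10; confounding rejection and
detection power on 200 simulated genes each; variance-component patterns on
a 2000-gene mixture; pathway distances against breadth-first search on 100
random digraphs of up to 50 nodes; breakpoint recovery on 100 seeded
200-probe step signals (250 permutations per split); eQTL family-wise error
on 100 permutation-null replicates of a 50-gene x 10-SNP scan, checked with
a one-sided binomial test against the nominal 5%; and lossless round trips
for every on-disk format. `scripts/acceptance.R` recomputes the same
quantities from scratch against the installed package.

## Known limitations

- The filter is rule-based by design; it produces no genotype likelihoods
  and no quality scores for downstream recalibration.
- BAM/CRAM are not parsed; convert to text SAM first (`samtools view`).
- Pedigrees beyond trios, phasing, and de novo prioritization are out of
  scope, as are isoform deconvolution, TPM/FPKM variants, negative-binomial
  count models, surrogate-variable correction, absolute integer copy
  number, and GC/capture-bias correction.
- The eQTL scan fits each pair independently; no kinship or population
  structure correction is attempted.
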