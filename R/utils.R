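# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

GENOTYPE_CATEGORIES <- c("hom_ref", "het_mut", "hom_mut", "qc")

# Allele encoding used throughout the package:
#   SNV        : the alternate base, e.g. "A"
#   insertion  : "+SEQ", the sequence inserted after the anchored position
#   deletion   : "-L",   L reference bases deleted starting at this position
is_indel_allele <- function(allele) {
  startsWith(allele, "+") | startsWith(allele, "-")
}

is_deletion_allele <- function(allele) startsWith(allele, "-")

is_base_allele <- function(allele) !is_indel_allele(allele)

# Ordering used for candidate-allele tie breaks: A < C < G < T < indels,
# indels among themselves lexicographically.
allele_rank <- function(allele) {
  base_rank <- match(allele, BASES)
  ifelse(is.na(base_rank), 5L, base_rank)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Phred string (offset 33) -> integer vector
phred_to_int <- function(qual) {
  if (is.na(qual) || identical(qual, "*")) return(NULL)
  as.integer(charToRaw(qual)) - 33L
}

int_to_phred <- function(q) {
  rawToChar(as.raw(q + 33L))
}

assert_tbl_has <- function(tbl, cols, what = "input") {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(tbl)
}

# One-letter -> three-letter amino acid names, as printed in annotation output
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

aa3 <- function(aa1) unname(AA3[aa1])
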