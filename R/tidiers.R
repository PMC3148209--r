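# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname gcdeg_test
#' @param x A `seqmine_gcdeg` object.
#' @param ... Unused.
#' @export
tidy.seqmine_gcdeg <- function(x, ...) {
  tibble(feature_id = x$feature_id,
         term = c("treatment (uncontrolled)", "treatment (controlled)"),
         p.value = c(x$p_unadjusted, x$p_adjusted))
}

#' @rdname gcdeg_test
#' @export
glance.seqmine_gcdeg <- function(x, ...) {
  vc <- setNames(x$variance_components$fraction, x$variance_components$component)
  tibble(feature_id = x$feature_id, n = x$n, m_snps = x$m_snps,
         p_unadjusted = x$p_unadjusted, p_adjusted = x$p_adjusted,
         is_gcdeg = x$is_gcdeg, var_genotype = vc[["genotype"]],
         var_treatment = vc[["treatment"]], var_residual = vc[["residual"]])
}

#' @rdname exon_qc
#' @param x An `exon_qc_report`.
#' @param ... Unused.
#' @export
tidy.exon_qc_report <- function(x, ...) {
  as_tibble(x$exons)
}

#' @rdname exon_qc
#' @export
glance.exon_qc_report <- function(x, ...) {
  tibble(mde = x$mde, ec5 = x$ec5, ec10 = x$ec10,
         coverage_specificity = x$coverage_specificity,
         n_exons = nrow(x$exons),
         n_defective = nrow(x$defective_regions))
}
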