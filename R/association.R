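# Differential expression, genotype-controlled differential expression,
# variance-component decomposition and eQTL scanning.
#
# Models, per gene with expression e over n samples:
#   uncontrolled : e_i = b0 + b  * tr_i + eps_i
#   controlled   : e_i = b0 + sum_j b_j * SNP_ij + b' * tr_i + eps_i
# tr is the two-level treatment, SNP_ij the additive 0/1/2 genotype code of
# the j-th SNP inside the gene. The slope test of the uncontrolled model is
# numerically identical to the pooled-variance two-sample t-test. A gene is a
# genotype-controlled DEG (GCDEG) when both slope tests are significant.

#' Two-group differential expression tests
#'
#' For every feature computes the log2 fold change of group means (with a
#' pseudocount), the equal-variance Student's t-test p-value, the Wilcoxon
#' rank-sum p-value and the Benjamini-Hochberg FDR over all tested features.
#' Fold changes and tests are oriented as second treatment level versus the
#' first (alphabetical when not a factor).
#'
#' @param expr Expression matrix tibble: `feature_id` plus one column per
#'   sample (e.g. RPKM from [phenotype_matrix()]).
#' @param design Tibble with `sample` and `treatment` (exactly two groups,
#'   each with at least two samples).
#' @param pseudocount Added to both group means before the ratio (default 0.5).
#' @return Tibble with `feature_id`, `log2_fold_change`, `t_pvalue`,
#'   `wilcoxon_pvalue`, `fdr`.
#' @export
deg_test <- function(expr, design, pseudocount = 0.5) {
  assert_tbl_has(design, c("sample", "treatment"), "design")
  groups <- split(design$sample, factor(design$treatment))
  if (length(groups) != 2) abort("deg_test requires exactly 2 treatment groups")
  if (any(lengths(groups) < 2)) abort("each treatment group needs >= 2 samples")
  missing <- setdiff(unlist(groups), names(expr))
  if (length(missing) > 0) {
    abort(sprintf("design sample(s) not in expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  g1 <- as.matrix(expr[groups[[1]]])
  g2 <- as.matrix(expr[groups[[2]]])
  res <- purrr::map(seq_len(nrow(expr)), function(i) {
    x <- g1[i, ]; y <- g2[i, ]
    tp <- tryCatch(t.test(y, x, var.equal = TRUE)$p.value,
                   error = function(e) NA_real_)
    wp <- tryCatch(suppressWarnings(wilcox.test(y, x)$p.value),
                   error = function(e) NA_real_)
    tibble(log2_fold_change = log2((mean(y) + pseudocount) /
                                   (mean(x) + pseudocount)),
           t_pvalue = tp, wilcoxon_pvalue = wp)
  }) |> bind_rows()
  tibble(feature_id = expr$feature_id) |>
    bind_cols(res) |>
    mutate(fdr = p.adjust(.data$t_pvalue, method = "BH"))
}

#' Genotype-controlled differential expression test for one gene
#'
#' Fits the uncontrolled model (treatment only) and the controlled model with
#' the gene's SNP genotype codes as covariates entered before treatment. A
#' treatment coefficient that is perfectly aliased by the genotype covariates
#' (complete confounding) yields an adjusted p-value of 1. With zero SNPs the
#' adjusted p-value equals the unadjusted one exactly.
#'
#' @param e Numeric expression values, one per sample.
#' @param treatment Two-level treatment vector aligned with `e`.
#' @param snps Numeric matrix (samples x m SNPs) of additive genotype codes,
#'   or `NULL` for m = 0. Requires `length(e) >= m + 3`.
#' @param alpha Significance cutoff applied to both tests (default 0.01).
#' @param feature_id Optional label carried into the result.
#' @return A `seqmine_gcdeg` object; see [generics::tidy()] /
#'   [generics::glance()] for tabular access. Fields: `p_unadjusted`,
#'   `p_adjusted`, `is_gcdeg`, `variance_components`.
#' @export
gcdeg_test <- function(e, treatment, snps = NULL, alpha = 0.01,
                       feature_id = NA_character_) {
  n <- length(e)
  if (is.null(snps)) snps <- matrix(numeric(0), nrow = n, ncol = 0)
  snps <- as.matrix(snps)
  m <- ncol(snps)
  if (m + 2 >= n) {
    abort(sprintf("n = %d samples cannot support m = %d SNP covariates; reduce the covariate set", n, m))
  }
  tr <- factor(treatment)
  if (nlevels(tr) != 2) abort("treatment must have exactly 2 levels")
  fit1 <- lm(e ~ tr)
  p_un <- slope_pvalue(fit1, "tr")
  if (m == 0) {
    fit2 <- fit1
    p_adj <- p_un
  } else {
    colnames(snps) <- paste0("snp", seq_len(m))
    df <- data.frame(e = e, snps, tr = tr)
    fit2 <- lm(stats::as.formula(
      paste("e ~", paste(c(colnames(snps), "tr"), collapse = " + "))), data = df)
    p_adj <- slope_pvalue(fit2, "tr")
    if (is.na(coef(fit2)[["tr" %+% levels(tr)[2]]])) p_adj <- 1.0
  }
  vc <- variance_components_fit(fit2, m)
  structure(list(feature_id = feature_id, n = n, m_snps = m,
                 p_unadjusted = p_un, p_adjusted = p_adj,
                 is_gcdeg = isTRUE(p_un < alpha) && isTRUE(p_adj < alpha),
                 alpha = alpha, variance_components = vc,
                 fit_uncontrolled = fit1, fit_controlled = fit2),
            class = "seqmine_gcdeg")
}

`%+%` <- function(a, b) paste0(a, b)

slope_pvalue <- function(fit, term_prefix) {
  sm <- summary(fit)$coefficients
  row <- grep(paste0("^", term_prefix), rownames(sm), value = TRUE)
  if (length(row) == 0) return(NA_real_)
  p <- sm[row[1], "Pr(>|t|)"]
  if (is.nan(p)) NA_real_ else p
}

#' @export
print.seqmine_gcdeg <- function(x, ...) {
  cat(sprintf("<gcdeg> %s: p_unadjusted = %.3g, p_adjusted = %.3g, GCDEG: %s (m = %d SNPs, n = %d)\n",
              x$feature_id, x$p_unadjusted, x$p_adjusted, x$is_gcdeg, x$m_snps, x$n))
  invisible(x)
}

#' Sequential variance-component decomposition of the controlled model
#'
#' Decomposes the total sum of squares of the controlled fit into the
#' genotype block (all SNP covariates, entered first), treatment, and
#' residual, each as a fraction of the total. Fractions sum to 1.
#'
#' @param e,treatment,snps As in [gcdeg_test()].
#' @return Tibble with `component` (genotype, treatment, residual) and
#'   `fraction`.
#' @export
variance_components <- function(e, treatment, snps = NULL) {
  n <- length(e)
  if (is.null(snps)) snps <- matrix(numeric(0), nrow = n, ncol = 0)
  snps <- as.matrix(snps)
  m <- ncol(snps)
  tr <- factor(treatment)
  if (m == 0) {
    fit <- lm(e ~ tr)
  } else {
    colnames(snps) <- paste0("snp", seq_len(m))
    df <- data.frame(e = e, snps, tr = tr)
    fit <- lm(stats::as.formula(
      paste("e ~", paste(c(colnames(snps), "tr"), collapse = " + "))), data = df)
  }
  variance_components_fit(fit, m)
}

variance_components_fit <- function(fit, m) {
  # only the sequential sums of squares are used; the F-tests anova() warns
  # about on perfect fits are irrelevant here
  an <- suppressWarnings(anova(fit))
  ss <- setNames(an$`Sum Sq`, rownames(an))
  total <- sum(ss)
  if (total <= .Machine$double.eps * length(fit$residuals)) {
    warn("zero total variance; returning all-zero variance components")
    return(tibble(component = c("genotype", "treatment", "residual"),
                  fraction = c(0, 0, 0)))
  }
  snp_terms <- grep("^snp", names(ss), value = TRUE)
  tibble(component = c("genotype", "treatment", "residual"),
         fraction = c(sum(ss[snp_terms]) / total,
                      sum(ss[grep("^tr$", names(ss))]) / total,
                      ss[["Residuals"]] / total))
}

#' Genotype-controlled DEG scan over an expression matrix
#'
#' Runs [gcdeg_test()] for every feature, using the SNPs mapped to it.
#' SNPs with missing genotype codes in any used sample are dropped from the
#' covariate set for that gene.
#'
#' @param expr Expression matrix tibble (`feature_id` + samples).
#' @param design Tibble with `sample`, `treatment`.
#' @param genotypes Coded genotype tibble: `snp_id` plus one 0/1/2 column per
#'   sample (see [code_genotypes()]).
#' @param gene_snps Tibble mapping `feature_id` to `snp_id` (m SNPs per gene).
#' @param alpha Significance cutoff for both tests (default 0.01).
#' @return Tibble with `feature_id`, `m_snps`, `p_unadjusted`, `p_adjusted`,
#'   `is_gcdeg` and the variance fractions `var_genotype`, `var_treatment`,
#'   `var_residual`.
#' @export
gcdeg_scan <- function(expr, design, genotypes, gene_snps, alpha = 0.01) {
  samples <- design$sample
  purrr::map(seq_len(nrow(expr)), function(i) {
    fid <- expr$feature_id[i]
    e <- as.numeric(expr[i, samples])
    snp_ids <- gene_snps$snp_id[gene_snps$feature_id == fid]
    snps <- NULL
    if (length(snp_ids) > 0) {
      g <- genotypes[match(snp_ids, genotypes$snp_id), samples, drop = FALSE]
      snps <- t(as.matrix(g))
      snps <- snps[, colSums(is.na(snps)) == 0, drop = FALSE]
      if (ncol(snps) == 0) snps <- NULL
    }
    res <- gcdeg_test(e, design$treatment, snps, alpha = alpha, feature_id = fid)
    vc <- setNames(res$variance_components$fraction,
                   res$variance_components$component)
    tibble(feature_id = fid, m_snps = res$m_snps,
           p_unadjusted = res$p_unadjusted, p_adjusted = res$p_adjusted,
           is_gcdeg = res$is_gcdeg,
           var_genotype = vc[["genotype"]], var_treatment = vc[["treatment"]],
           var_residual = vc[["residual"]])
  }) |> bind_rows()
}

#' Code genotype categories additively
#'
#' `hom_ref` -> 0, `het_mut` -> 1, `hom_mut` -> 2, `qc` -> `NA`.
#'
#' @param m Genotype matrix from [aggregate_genotypes()].
#' @return Tibble with `snp_id` (`chrom:pos_ref>alt`, positions 1-based) plus
#'   one numeric column per sample.
#' @export
code_genotypes <- function(m) {
  code <- c(hom_ref = 0, het_mut = 1, hom_mut = 2, qc = NA_real_)
  samples <- setdiff(names(m), c("chrom", "pos", "ref", "alt"))
  out <- tibble(snp_id = sprintf("%s:%d_%s>%s", m$chrom, m$pos + 1L, m$ref, m$alt))
  for (s in samples) out[[s]] <- unname(code[m[[s]]])
  out
}

#' Scan for cis and trans eQTLs
#'
#' For every (gene, SNP) pair, regresses expression on the additive genotype
#' code by simple linear regression; p-values are Bonferroni-adjusted over
#' the number of tests actually performed. A pair is cis when the SNP lies
#' within the gene span extended by `cis_window` on both sides, trans
#' otherwise. Monomorphic SNPs and pairs with fewer than 3 complete samples
#' are skipped.
#'
#' @param expr Expression matrix tibble (`feature_id` + samples).
#' @param genotypes Coded genotype tibble (`snp_id` + samples, values 0/1/2
#'   or `NA`); `NA` cells are excluded pairwise.
#' @param gene_loci Tibble with `feature_id`, `chrom`, `start`, `end`.
#' @param snp_loci Tibble with `snp_id`, `chrom`, `pos`.
#' @param mode `"both"`, `"cis"` or `"trans"`.
#' @param cis_window Bases around the gene span that still count as cis
#'   (default 1e6).
#' @return Tibble with `feature_id`, `snp_id`, `n`, `beta`, `pvalue`,
#'   `adjusted_pvalue`, `relation`.
#' @export
eqtl_scan <- function(expr, genotypes, gene_loci, snp_loci,
                      mode = c("both", "cis", "trans"), cis_window = 1e6) {
  mode <- match.arg(mode)
  samples <- intersect(setdiff(names(expr), "feature_id"),
                       setdiff(names(genotypes), "snp_id"))
  if (length(samples) < 3) abort("need >= 3 shared samples between matrices")
  pairs <- tidyr::crossing(feature_id = expr$feature_id,
                           snp_id = genotypes$snp_id) |>
    left_join(gene_loci, by = "feature_id") |>
    left_join(rename(snp_loci, snp_chrom = "chrom"), by = "snp_id") |>
    mutate(relation = if_else(
      !is.na(.data$chrom) & !is.na(.data$snp_chrom) &
        .data$chrom == .data$snp_chrom &
        .data$pos >= .data$start - cis_window &
        .data$pos < .data$end + cis_window, "cis", "trans"))
  if (mode != "both") pairs <- filter(pairs, .data$relation == mode)
  emat <- as.matrix(expr[samples]); rownames(emat) <- expr$feature_id
  gmat <- as.matrix(genotypes[samples]); rownames(gmat) <- genotypes$snp_id
  gi <- match(pairs$feature_id, rownames(emat))
  si <- match(pairs$snp_id, rownames(gmat))
  np <- nrow(pairs)
  n_used <- integer(np); beta <- numeric(np); pval <- numeric(np)
  ok <- logical(np)
  for (i in seq_len(np)) {
    y <- emat[gi[i], ]
    x <- gmat[si[i], ]
    cc <- !(is.na(x) | is.na(y))
    x <- x[cc]; y <- y[cc]
    n <- length(x)
    if (n < 3) next
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    if (sxx == 0) next                      # monomorphic SNP: skipped
    syy <- sum((y - my)^2)
    sxy <- sum((x - mx) * (y - my))
    ok[i] <- TRUE
    n_used[i] <- n
    beta[i] <- sxy / sxx
    r2 <- if (syy == 0) 0 else (sxy * sxy) / (sxx * syy)
    pval[i] <- if (r2 >= 1) 0 else {
      2 * pt(sqrt(r2 * (n - 2) / (1 - r2)), df = n - 2, lower.tail = FALSE)
    }
  }
  res <- tibble(feature_id = pairs$feature_id[ok], snp_id = pairs$snp_id[ok],
                n = n_used[ok], beta = beta[ok], pvalue = pval[ok],
                relation = pairs$relation[ok])
  mutate(res, adjusted_pvalue = pmin(1, .data$pvalue * nrow(res))) |>
    select("feature_id", "snp_id", "n", "beta", "pvalue",
           "adjusted_pvalue", "relation")
}
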