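# DEG testing, genotype-controlled DEG, variance components and eQTL.

design20 <- tibble::tibble(sample = sprintf("S%02d", 1:20),
                           treatment = rep(c("control", "treated"), each = 10))

expr_row <- function(values, samples = design20$sample) {
  tibble::tibble(feature_id = "g1", !!!stats::setNames(as.list(values), samples))
}

test_that("a symmetric two-point configuration gives a unit t p-value", {
  d <- tibble::tibble(sample = c("a", "b", "c", "d"),
                      treatment = c("x", "x", "y", "y"))
  expr <- tibble::tibble(feature_id = "g1", a = 1, b = 2, c = 2, d = 1)
  res <- deg_test(expr, d)
  expect_equal(res$t_pvalue, 1, tolerance = 1e-12)
  expect_equal(res$log2_fold_change, 0)
})

test_that("a clean two-fold shift is detected with the textbook t formula", {
  d <- tibble::tibble(sample = sprintf("s%d", 1:6),
                      treatment = rep(c("ctl", "trt"), each = 3))
  jit <- c(-1e-4, 0, 1e-4)
  expr <- tibble::tibble(feature_id = "g1",
                         !!!stats::setNames(as.list(c(1 + jit, 2 + jit)),
                                            sprintf("s%d", 1:6)))
  res <- deg_test(expr, d, pseudocount = 0)
  expect_lt(res$t_pvalue, 1e-6)
  expect_equal(res$log2_fold_change, 1, tolerance = 1e-3)
  # oracle: textbook pooled t statistic
  x <- 1 + jit; y <- 2 + jit
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  tstat <- (mean(y) - mean(x)) / (sp * sqrt(1 / 3 + 1 / 3))
  want <- 2 * stats::pt(abs(tstat), df = 4, lower.tail = FALSE)
  expect_equal(res$t_pvalue, want, tolerance = 1e-10)
})

test_that("FDR equals a hand Benjamini-Hochberg computation", {
  withr::local_seed(61)
  expr <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    vals <- rnorm(20) + (i <= 4) * i * 0.4 * (design20$treatment == "treated")
    dplyr::mutate(expr_row(vals), feature_id = sprintf("g%d", i))
  }))
  res <- deg_test(expr, design20)
  p <- res$t_pvalue
  n <- length(p)
  o <- order(p)
  hand <- numeric(n)
  hand[o[n]] <- p[o[n]] * n / n
  for (k in (n - 1):1) {
    hand[o[k]] <- min(p[o[k]] * n / k, hand[o[k + 1]])
  }
  expect_equal(res$fdr, hand, tolerance = 1e-12)
  # BH is monotone along the sorted p-values
  expect_true(all(diff(res$fdr[o]) >= -1e-15))
})

test_that("the uncontrolled slope test equals the pooled-variance t-test", {
  withr::local_seed(62)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    tr <- rep(c("a", "b"), length.out = n)
    e <- rnorm(n, sd = runif(1, 0.5, 3)) +
      (tr == "b") * rnorm(1, 0, 1.5)
    fit <- gcdeg_test(e, tr, NULL)
    want <- t.test(e[tr == "b"], e[tr == "a"], var.equal = TRUE)$p.value
    expect_equal(fit$p_unadjusted, want, tolerance = 1e-10)
    expect_identical(fit$p_adjusted, fit$p_unadjusted)   # m = 0 collapse
  }
})

test_that("complete confounding suppresses the adjusted test", {
  withr::local_seed(63)
  tr <- design20$treatment
  snp <- matrix(ifelse(tr == "treated", 2, 0), ncol = 1)
  e <- 5 + 1.5 * snp[, 1] + rnorm(20, 0, 0.5)
  fit <- gcdeg_test(e, tr, snp)
  expect_lt(fit$p_unadjusted, 0.01)
  expect_identical(fit$p_adjusted, 1.0)
  expect_false(fit$is_gcdeg)
  g <- glance(fit)
  expect_equal(g$p_adjusted, 1.0)
  expect_equal(g$var_treatment, 0)
})

test_that("orthogonal genotype leaves the treatment slope unbiased", {
  withr::local_seed(64)
  biases <- purrr::map_dbl(1:100, function(i) {
    tr <- design20$treatment
    snp <- matrix(rbinom(20, 2, 0.4), ncol = 1)
    e <- 5 + 2 * (tr == "treated") + 0.8 * snp[, 1] + rnorm(20, 0, 1)
    fit <- gcdeg_test(e, tr, snp)
    coef(fit$fit_controlled)[["trtreated"]] - 2
  })
  expect_lt(abs(mean(biases)), 0.1)
})

test_that("variance fractions sum to one and track the generating model", {
  tr <- design20$treatment
  snp <- matrix(rep(c(0, 1, 2, 1), 5), ncol = 1)
  # expression purely linear in the SNP: genotype fraction ~ 1
  vc <- variance_components(3 + 2 * snp[, 1], tr, snp)
  expect_equal(sum(vc$fraction), 1, tolerance = 1e-9)
  expect_gt(vc$fraction[vc$component == "genotype"], 0.99)
  # pure treatment effect, genotype orthogonal
  withr::local_seed(65)
  e <- 1 + 3 * (tr == "treated") + rnorm(20, 0, 0.3)
  vc2 <- variance_components(e, tr, snp)
  expect_gt(vc2$fraction[vc2$component == "treatment"], 0.8)
  # pure noise at large n: residual fraction -> 1
  n <- 400
  vc3 <- variance_components(rnorm(n), rep(c("a", "b"), n / 2),
                             matrix(rbinom(n, 2, 0.3), ncol = 1))
  expect_gt(vc3$fraction[vc3$component == "residual"], 0.95)
  expect_warning(variance_components(rep(1, 20), tr, snp), "zero total variance")
})

test_that("over-parameterized covariate sets are rejected", {
  expect_error(gcdeg_test(rnorm(6), rep(c("a", "b"), 3),
                          matrix(rnorm(24), nrow = 6)), "covariate")
})

test_that("eQTL regression matches lm and classifies cis/trans by locus", {
  expr <- tibble::tibble(feature_id = "gene1",
                         !!!stats::setNames(as.list(1 + 0.5 * c(0, 1, 2, 0, 1, 2)),
                                            sprintf("S%d", 1:6)))
  geno <- tibble::tibble(snp_id = c("snpA", "snpB"),
                         !!!stats::setNames(
                           purrr::map(1:6, ~ c(c(0, 1, 2, 0, 1, 2)[.x], 1)),
                           sprintf("S%d", 1:6)))
  gene_loci <- tibble::tibble(feature_id = "gene1", chrom = "chr22",
                              start = 1e6, end = 1.1e6)
  snp_loci <- tibble::tibble(snp_id = c("snpA", "snpB"),
                             chrom = c("chr11", "chr22"),
                             pos = c(5e6, 1.05e6))
  res <- eqtl_scan(expr, geno, gene_loci, snp_loci)
  expect_equal(nrow(res), 1)                       # snpB monomorphic, skipped
  expect_equal(res$beta, 0.5, tolerance = 1e-12)
  expect_lt(res$pvalue, 1e-12)
  expect_equal(res$relation, "trans")              # chr11 SNP, chr22 gene
  # random data: closed form equals the lm oracle, Bonferroni = m * p
  withr::local_seed(66)
  samples <- sprintf("S%02d", 1:15)
  expr2 <- tibble::tibble(feature_id = c("gA", "gB"),
                          !!!stats::setNames(purrr::map(1:15, ~ rnorm(2)), samples))
  geno2 <- tibble::tibble(snp_id = c("s1", "s2", "s3"),
                          !!!stats::setNames(
                            purrr::map(1:15, ~ rbinom(3, 2, 0.5)), samples))
  loci_g <- tibble::tibble(feature_id = c("gA", "gB"), chrom = "chr1",
                           start = c(1e5, 9e6), end = c(2e5, 9.1e6))
  loci_s <- tibble::tibble(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                           pos = c(1.5e5, 5e6, 2e7))
  res2 <- eqtl_scan(expr2, geno2, loci_g, loci_s)
  for (k in seq_len(nrow(res2))) {
    y <- as.numeric(expr2[expr2$feature_id == res2$feature_id[k], samples])
    x <- as.numeric(geno2[geno2$snp_id == res2$snp_id[k], samples])
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(res2$beta[k], fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(res2$pvalue[k], fit["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(res2$adjusted_pvalue, pmin(1, res2$pvalue * nrow(res2)))
  expect_equal(res2$relation[res2$feature_id == "gA" & res2$snp_id == "s1"], "cis")
})

test_that("qc genotype cells are excluded pairwise", {
  m <- tibble::tibble(chrom = "chr1", pos = c(0L, 1L), ref = "A", alt = "G",
                      s1 = c("het_mut", "qc"), s2 = c("hom_mut", "hom_ref"))
  coded <- code_genotypes(m)
  expect_equal(coded$s1, c(1, NA))
  expect_equal(coded$s2, c(2, 0))
  expect_equal(coded$snp_id[1], "chr1:1_A>G")
})
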