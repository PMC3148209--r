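# ggplot2 visual summaries of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage track region
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome to plot.
#' @param from,to 0-based half-open window (defaults to the whole chromosome).
#' @return A ggplot object.
#' @export
plot_coverage <- function(track, chrom, from = 0L, to = NULL) {
  depth <- track[[chrom]]
  if (is.null(depth)) abort(sprintf("chromosome '%s' not in track", chrom))
  to <- to %||% length(depth)
  df <- tibble(pos = seq.int(from + 1L, to), depth = depth[(from + 1L):to])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom), y = "read depth") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression results
#'
#' @param object A tibble from [deg_test()].
#' @param alpha FDR threshold used for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seqmine_deg <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = -log10(.data$t_pvalue),
                               colour = .data$fdr < alpha)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("FDR < %g", alpha)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 t-test p") +
    ggplot2::theme_minimal()
}

#' Plot expression against treatment and genotype for one gene
#'
#' The diagnostic view for genotype-confounded differential expression: one
#' panel per genotype code, expression by treatment group.
#'
#' @param e Expression values.
#' @param treatment Treatment labels.
#' @param snp Genotype codes (0/1/2) of one SNP.
#' @return A ggplot object.
#' @export
plot_gcdeg <- function(e, treatment, snp) {
  df <- tibble(e = e, treatment = treatment,
               genotype = factor(snp, levels = 0:2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$treatment, y = .data$e)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.8,
                         ggplot2::aes(colour = .data$genotype)) +
    ggplot2::labs(y = "expression") +
    ggplot2::theme_minimal()
}

#' Plot probe signals with fitted CBS segments
#'
#' @param object A `cbs_segments` tibble from [cbs_segment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbs_segments <- function(object, ...) {
  probes <- attr(object, "signals")
  p <- ggplot2::ggplot()
  if (!is.null(probes)) {
    p <- p + ggplot2::geom_point(
      data = probes,
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$value),
      colour = "grey50", size = 0.6)
  }
  p +
    ggplot2::geom_segment(
      data = as_tibble(object),
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$segment_mean, yend = .data$segment_mean),
      colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genomic position", y = "log2 ratio") +
    ggplot2::theme_minimal()
}
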