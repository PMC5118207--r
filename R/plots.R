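#' Volcano-style plot of a per-gene association result
#'
#' Odds ratio (log scale) against `-log10` raw p per gene, with the
#' Bonferroni-equivalent raw-p threshold drawn as a dashed line and
#' significant genes labelled.
#'
#' @param object A `"burden_assoc"` object from [associate_genes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot burden_assoc
#' @export
autoplot.burden_assoc <- function(object, ...) {
  df <- tidy(object)
  thr <- glance(object)$p_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = -log10(.data$p_raw))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::geom_text(
      data = filter(df, .data$significant),
      ggplot2::aes(label = .data$gene),
      vjust = -0.8, size = 3
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c("FALSE" = "grey40", "TRUE" = "firebrick"), guide = "none") +
    ggplot2::labs(
      x = "Odds ratio (capture-adjusted allele counts)",
      y = expression(-log[10] ~ "raw p"),
      title = "Per-gene rare-variant burden enrichment",
      subtitle = sprintf("Bonferroni threshold %.3g over %d genes",
                         thr, glance(object)$n_tests)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of per-gene mutational loads by cohort
#'
#' @param burdens Tibble from [burden_by_gene()].
#' @param genes Optional subset of genes to show; default the 15 genes with
#'   the highest case load.
#' @return A ggplot.
#' @export
plot_gene_loads <- function(burdens, genes = NULL) {
  if (is.null(genes)) {
    genes <- burdens |>
      filter(.data$cohort == "case") |>
      arrange(dplyr::desc(.data$load)) |>
      head(15) |>
      pull("gene")
  }
  df <- filter(burdens, .data$gene %in% genes) |>
    mutate(gene = factor(.data$gene, levels = genes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = 100 * .data$load,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Mutational load (%)", fill = NULL,
                  title = "Capture-adjusted mutational load by gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
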