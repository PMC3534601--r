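#' Volcano plot of a per-tissue screen
#'
#' Mean female/male log2 fold-change against -log10 Wilcoxon p, the
#' standard overview of a sex-bias screen, optionally faceted by chromosome
#' class when an annotation is supplied.
#'
#' @param results A [test_tissue()] or [test_experiment()] result.
#' @param ann Optional probe annotation for chromosome-class facets.
#' @param alpha Threshold drawn as a horizontal guide.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, ann = NULL, alpha = 0.001) {
  df <- results
  if (!is.null(ann)) {
    df <- left_join(df, select(ann, "probe_id", "chrom_class"), by = "probe_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                        y = -log10(pmax(.data$p_wilcoxon, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(female = "#c0392b", male = "#2e6da4",
                                            ns = "grey60")) +
    ggplot2::labs(x = expression(log[2] ~ "fold-change (F/M)"),
                  y = expression(-log[10] ~ "p (Wilcoxon)"), colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ann)) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$chrom_class))
  if ("tissue" %in% names(df) && n_distinct(df$tissue) > 1) {
    p <- p + ggplot2::facet_grid(
      rows = if (!is.null(ann)) ggplot2::vars(.data$chrom_class) else NULL,
      cols = ggplot2::vars(.data$tissue))
  }
  p
}

#' Bar chart of biased-probe percentages by chromosome class
#'
#' @param counts A [tabulate_bias()] (or [fixture_counts()]) table.
#' @return A ggplot object.
#' @export
plot_bias_counts <- function(counts) {
  long <- tidyr::pivot_longer(
    select(counts, "tissue", "chrom_class", "pct_female", "pct_male"),
    cols = c("pct_female", "pct_male"),
    names_to = "direction", values_to = "pct")
  long <- mutate(long, direction = sub("^pct_", "", .data$direction))
  ggplot2::ggplot(filter(long, .data$chrom_class %in% c("A", "X")),
                  ggplot2::aes(x = .data$chrom_class, y = .data$pct,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(female = "#c0392b", male = "#2e6da4")) +
    ggplot2::labs(x = NULL, y = "% of probes biased", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-branch sex-bias proportions
#'
#' @param proportions A [branch_proportions()] table.
#' @return A ggplot object; excluded branches are dropped.
#' @export
plot_branch_proportions <- function(proportions) {
  long <- tidyr::pivot_longer(filter(proportions, .data$included),
                              cols = c("prop_female", "prop_male"),
                              names_to = "direction", values_to = "prop")
  long <- mutate(long, direction = sub("^prop_", "", .data$direction))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$branch), y = .data$prop,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(female = "#c0392b", male = "#2e6da4")) +
    ggplot2::labs(x = "phylogenetic branch (0 = oldest)",
                  y = "proportion of probes biased", fill = NULL) +
    ggplot2::theme_minimal()
}
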