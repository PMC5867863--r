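#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_vline labs theme_minimal scale_color_manual
#' @export
ggplot2::autoplot

#' Volcano plot of a DE result
#'
#' @param object A `wean_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wean_de <- function(object, ...) {
  d <- tidy(object)
  g <- attr(object, "groups")
  ggplot(d, aes(x = .data$log2FC, y = -log10(.data$p), color = .data$significant)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed", linewidth = 0.3) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(
      x = bquote(log[2] ~ "fold change (" * .(unname(g["b"])) ~ "vs" ~ .(unname(g["a"])) * ")"),
      y = expression(-log[10] ~ p), color = "p.BH < 0.05"
    ) +
    theme_minimal()
}

#' MA plot of a DE result
#'
#' @param de A `wean_de` object.
#' @return A ggplot of log2FC against mean normalized count.
#' @export
plot_ma <- function(de) {
  d <- tidy(de)
  ggplot(d, aes(x = .data$baseMean, y = .data$log2FC, color = .data$significant)) +
    geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "mean normalized count", y = expression(log[2] ~ "fold change")) +
    theme_minimal()
}

#' Distance-correlation plot of cis-target calls
#'
#' @param object A `wean_cis` object.
#' @param ... Unused.
#' @return A ggplot of Pearson r against lncRNA-gene distance.
#' @export
autoplot.wean_cis <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$distance_bp / 1000, y = .data$r, color = .data$is_cis_target)) +
    geom_point(alpha = 0.6, size = 0.9) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "lncRNA-gene distance (kb)", y = "Pearson r", color = "cis target") +
    theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' @param object A `wean_enrich` object.
#' @param ... Unused.
#' @param top Number of top sets to show.
#' @return A ggplot.
#' @export
autoplot.wean_enrich <- function(object, top = 15, ...) {
  d <- utils::head(tidy(object), top)
  d$set_name <- factor(d$set_name, levels = rev(d$set_name))
  ggplot(d, aes(
    x = -log10(.data$p_adj), y = .data$set_name,
    size = .data$overlap, color = .data$significant
  )) +
    geom_point() +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = expression(-log[10] ~ "adjusted p"), y = NULL, size = "overlap") +
    theme_minimal()
}

#' Length-bin histogram of discovered lncRNAs
#'
#' @param discovery A `wean_discovery` tibble.
#' @return A ggplot of transcript counts per length bin.
#' @export
plot_length_bins <- function(discovery) {
  bins <- characterize_lncrnas(discovery)$length_bins
  ggplot(bins, aes(x = .data$bin, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "transcript length (bp)", y = "lncRNA transcripts") +
    theme_minimal()
}
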