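#' Volcano plot of a differential-expression result
#'
#' @param object An `sbg_de` from [run_de()].
#' @param alpha FDR threshold drawn as a dashed line (defaults to the run's).
#' @param ... Unused.
#' @return A ggplot: LFC (male vs female) against -log10 adjusted p, FBGs in
#'   red, MBGs in blue.
#' @export
autoplot.sbg_de <- function(object, alpha = attr(object, "alpha") %||% 0.05, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$padj), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$bias_class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(FBG = "#c0392b", MBG = "#2c5f9e",
                                            unbiased = "grey60")) +
    ggplot2::labs(x = "log2 fold change (male / female)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an RRHO map
#'
#' @param object An `rrho_map`.
#' @param corrected Plot BY-corrected scores when available (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot tile map of signed -log10 p; the origin (rank 1 = most
#'   female-biased in both species) sits at the lower left, so concordant
#'   profiles light up along the diagonal.
#' @export
autoplot.rrho_map <- function(object, corrected = TRUE, ...) {
  df <- tidy(object)
  value <- if (corrected && "signed_score_by" %in% names(df)) "signed_score_by"
           else "signed_score"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold_a, y = .data$threshold_b,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2c5f9e", mid = "white", high = "#c0392b") +
    ggplot2::labs(x = "rank threshold, species A", y = "rank threshold, species B",
                  fill = "signed\n-log10 p") +
    ggplot2::theme_minimal()
}

#' Per-chromosome sex-biased gene proportions
#'
#' @param proportions Result of [sbg_proportions()].
#' @return A ggplot bar chart: FBG (red) and MBG (blue) proportions of
#'   expressed genes per chromosome, sex chromosomes outlined.
#' @export
plot_sbg_proportions <- function(proportions) {
  df <- tidyr::pivot_longer(proportions, c("prop_fbg", "prop_mbg"),
                            names_to = "bias", values_to = "proportion")
  df$bias <- ifelse(df$bias == "prop_fbg", "FBG", "MBG")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome, y = .data$proportion,
                                   fill = .data$bias,
                                   colour = .data$chrom_class == "sex_chromosome")) +
    ggplot2::geom_col(position = "dodge", linewidth = 0.6) +
    ggplot2::scale_fill_manual(values = c(FBG = "#c0392b", MBG = "#2c5f9e")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "proportion of expressed genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' PCA plot of samples
#'
#' @param pca An `sbg_pca` from [pca_qc()].
#' @param samples Optional sample tibble to colour by tissue and shape by
#'   sex.
#' @return A ggplot of the first two components with variance percentages in
#'   the axis labels.
#' @export
plot_pca <- function(pca, samples = NULL) {
  df <- pca$coordinates
  if (!is.null(samples)) df <- dplyr::left_join(df, samples, by = "sample_id")
  ve <- round(100 * pca$variance_explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(samples)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$tissue, shape = .data$sex),
                            size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                    y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
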