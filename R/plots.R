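#' Scree plot of a scaled PCA
#'
#' @param object A `song_pca` object.
#' @param ... Unused.
#' @return A ggplot: eigenvalue (squared component sdev) per component,
#'   with the proportion of total variance labelled.
#' @export
autoplot.song_pca <- function(object, ...) {
  d <- tidy.song_pca(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$prop_variance)), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Eigenvalue",
                  title = paste("Scaled PCA:", paste(object$subset, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Signal-strength overview plot
#'
#' Blomberg's K against Pagel's lambda for every trait in a signal table,
#' coloured by category; traits failing the randomization test at the
#' given level are hollow.
#'
#' @param table1 Signal table with `trait`, `category`, `K`, `P`, `lambda`.
#' @param alpha Randomization-test significance level.
#' @return A ggplot.
#' @export
plot_signal <- function(table1, alpha = 0.05) {
  ggplot2::ggplot(table1, ggplot2::aes(x = .data$lambda, y = .data$K,
                                       colour = .data$category,
                                       shape = .data$P < alpha)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = sprintf("P < %.2f", alpha)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey55") +
    ggplot2::labs(x = expression(hat(lambda)), y = "Blomberg's K") +
    ggplot2::theme_minimal()
}

#' Correlation heat map, raw or phylogenetically corrected
#'
#' @param cor_tbl Output of [correlate_traits()].
#' @param which `"raw"` or `"pic"`.
#' @param alpha Significance level for the star markers.
#' @return A ggplot tile map of correlation coefficients.
#' @export
plot_correlations <- function(cor_tbl, which = c("raw", "pic"),
                              alpha = 0.05) {
  which <- match.arg(which)
  cor_tbl$r <- cor_tbl[[paste0("r_", which)]]
  cor_tbl$p <- cor_tbl[[paste0("p_", which)]]
  ggplot2::ggplot(cor_tbl, ggplot2::aes(x = .data$trait, y = .data$predictor,
                                        fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$p < alpha, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = paste0("r (", which, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
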