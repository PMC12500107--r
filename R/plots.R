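#' Heatmap of a correlation matrix
#'
#' @param object A `cr_cormat` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot cr_cormat
autoplot.cr_cormat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Aggregate heatmap of a signal matrix
#'
#' Rows sorted by decreasing total signal, mirroring how aggregate
#' CUT&RUN heatmaps are usually displayed.
#'
#' @param object A `cr_matrix` from [signal_matrix()].
#' @param trim Upper quantile at which fill values are capped for display
#'   (default 0.98).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot cr_matrix
autoplot.cr_matrix <- function(object, trim = 0.98, ...) {
  ord <- order(rowSums(object$values), decreasing = TRUE)
  df <- tidy(object)
  df$row <- match(df$row_id, object$row_id[ord])
  cap <- stats::quantile(df$value, trim, names = FALSE)
  df$value <- pmin(df$value, cap)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "bin", y = "region (sorted by signal)", fill = "signal") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential table
#'
#' @param dt A `cr_diff` table from [classify_differential()].
#' @return A ggplot of log2 fold change against -log10 adjusted p, colored
#'   by class.
#' @export
plot_volcano <- function(dt) {
  ggplot2::ggplot(dt, ggplot2::aes(.data$log2fc, -log10(pmax(.data$adj_p, 1e-300)),
                                   color = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(increased = "#b2182b",
                                           decreased = "#2166ac",
                                           unchanged = "grey60")) +
    ggplot2::labs(x = "log2 fold change (late / early)",
                  y = "-log10 adjusted p", color = NULL) +
    ggplot2::theme_classic()
}

#' MA plot of a ratio table
#'
#' @param rt A tibble from [log2_ratio_table()].
#' @return A ggplot of M against A.
#' @export
plot_ma <- function(rt) {
  ggplot2::ggplot(rt, ggplot2::aes(.data$A, .data$M)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::labs(x = "A (mean log2 abundance)", y = "M (log2 late/early)") +
    ggplot2::theme_classic()
}
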