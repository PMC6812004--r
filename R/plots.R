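#' Plot a 2-D embedding colored by cluster
#'
#' @param coords Tibble from [tsne_embed()] (`barcode`, `tsne1`, `tsne2`).
#' @param labels An `eec_clusters` (optional).
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels = NULL) {
  df <- coords
  if (!is.null(labels))
    df <- left_join(df, as_tibble(labels), by = "barcode") |>
      mutate(cluster = factor(.data$cluster))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$tsne1, .data$tsne2)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (!is.null(labels))
    p + ggplot2::geom_point(ggplot2::aes(color = .data$cluster), size = 0.8)
  else p + ggplot2::geom_point(size = 0.8)
}

#' Heatmap of relative-to-average expression per cluster
#'
#' @param heat Long tibble from [heatmap_table()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(heat) {
  ggplot2::ggplot(heat, ggplot2::aes(factor(.data$cluster), .data$gene,
                                     fill = .data$relative_expression)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "cluster", y = NULL, fill = "relative\nexpression") +
    ggplot2::theme_minimal()
}

#' Violin plot of log2 normalized expression by cluster
#'
#' @param violin Long tibble from [violin_table()].
#' @return A ggplot object.
#' @export
plot_violin <- function(violin) {
  ggplot2::ggplot(violin, ggplot2::aes(factor(.data$cluster), .data$log2_numi)) +
    ggplot2::geom_violin(scale = "width", fill = "grey80") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "cluster", y = "log2(normalized UMIs + 1)") +
    ggplot2::theme_minimal()
}

#' @describeIn axis_correlation Scatter plot of the paired fold changes with
#'   the Pearson correlation annotated.
#' @param object An `eec_axis_cor`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.eec_axis_cor <- function(object, ...) {
  lab <- if (object$undefined) "r undefined"
         else sprintf("r = %.2f (n = %d)", object$pearson_r, object$n_genes)
  ggplot2::ggplot(object$genes, ggplot2::aes(.data$l2fc_x, .data$l2fc_y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = paste0("L2FC: ", object$comparison_x),
                  y = paste0("L2FC: ", object$comparison_y)) +
    ggplot2::theme_minimal()
}
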