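# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_line
#'   geom_point scale_fill_gradient2 labs theme_minimal facet_wrap
#'   geom_hline geom_vline coord_equal
#' @export
ggplot2::autoplot

#' Heatmap of neighbourhood-enrichment Z-scores
#'
#' @param object an [nhood_enrichment()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$label_a, y = .data$label_b, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#3b4cc0", mid = "white", high = "#b40426") +
    labs(x = NULL, y = NULL, fill = "Z") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Spatial map of domain labels
#'
#' @param object a [cluster_domains()] result.
#' @param table the cell tibble the domains were fit on (`x`, `y`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.domain_assignment <- function(object, table, ...) {
  tibble::tibble(x = table$x, y = table$y,
                 domain = factor(object$labels)) |>
    ggplot(aes(.data$x, .data$y, colour = .data$domain)) +
    geom_point(size = 0.4) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' Stacked cell-type composition bars per week
#'
#' @param comp a [composition()] tibble.
#' @return a ggplot.
#' @export
plot_composition <- function(comp) {
  type_col <- setdiff(names(comp), c("week", "n", "pct"))[1]
  ggplot(comp, aes(x = factor(.data$week), y = .data$pct,
                   fill = .data[[type_col]])) +
    geom_col() +
    labs(x = "week", y = "% of cells", fill = NULL) +
    theme_minimal()
}

#' Volcano-style view of a differential-marker table
#'
#' @param diff a [differential_markers()] tibble.
#' @param alpha,lfc the significance cut points to draw.
#' @return a ggplot.
#' @export
plot_differential_markers <- function(diff, alpha = 0.05, lfc = 1) {
  ggplot(diff, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                   colour = .data$significant)) +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$marker), vjust = -0.6, size = 3,
                       show.legend = FALSE) +
    geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = "log2 fold change", y = "-log10 adjusted p") +
    theme_minimal()
}

#' Time series of scaled adjacency enrichment
#'
#' @param series a [temporal_series()] tibble.
#' @return a ggplot.
#' @export
plot_temporal_series <- function(series) {
  ggplot(series, aes(x = .data$week, y = .data$scaled_z,
                     colour = .data$other, group = .data$other)) +
    geom_line() +
    facet_wrap(~focal) +
    labs(x = "week", y = "scaled Z") +
    theme_minimal()
}
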