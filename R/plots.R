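# ggplot2 views of the main result types.

#' Plot a contact map
#'
#' Log10 colour scale heat map of the (corrected or raw) contact matrix.
#'
#' @param map A `contact_map`.
#' @param region Optional bin range `c(from, to)` (0-based half-open).
#' @return A ggplot.
#' @export
plot_contact_map <- function(map, region = NULL) {
  n <- n_bins(map)
  if (is.null(region)) region <- c(0L, n)
  b <- (region[1] + 1L):region[2]
  d <- tidyr::expand_grid(i = b - 1L, j = b - 1L)
  d$value <- map$counts[cbind(d$i + 1L, d$j + 1L)]
  ggplot2::ggplot(d, ggplot2::aes(.data$i, .data$j,
                                  fill = log10(.data$value + 1e-9))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log10 contacts") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin", title = map$arm_id) +
    ggplot2::theme_minimal()
}

#' @rdname plot_contact_map
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.contact_map <- function(object, ...) plot_contact_map(object, ...)

#' Plot a saddle matrix
#'
#' @param s A `saddle_matrix` (or a subtraction of two).
#' @return A ggplot with PC1 quantiles on both axes.
#' @export
plot_saddle <- function(s) {
  d <- tidy(s)
  ggplot2::ggplot(d, ggplot2::aes(.data$quantile_col, .data$quantile_row,
                                  fill = .data$log2_enrichment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "log2 O/E") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "PC1 quantile", y = "PC1 quantile") +
    ggplot2::theme_minimal()
}

#' @rdname plot_saddle
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.saddle_matrix <- function(object, ...) plot_saddle(object)

#' Boxplots of per-group log2 fold changes
#'
#' @param tads Tibble with `group` and a value column (see
#'   [group_change_summary()]).
#' @param value Value column name.
#' @return A ggplot.
#' @export
plot_group_changes <- function(tads, value = "acf_log2fc") {
  ggplot2::ggplot(tads, ggplot2::aes(.data$group, .data[[value]],
                                     fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "TAD group (Jaccard rank)", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble distance map
#'
#' @param m Matrix from [ensemble_distance_map()].
#' @return A ggplot.
#' @export
plot_distance_map <- function(m) {
  d <- as.data.frame(as.table(m))
  names(d) <- c("i", "j", "distance")
  d$i <- as.integer(d$i); d$j <- as.integer(d$j)
  ggplot2::ggplot(d, ggplot2::aes(.data$i, .data$j, fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "mean distance") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "segment", y = "segment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
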