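#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

#' Plot a spatial assignment
#'
#' Scatter of cell positions colored by population; 3-D assignments are
#' faceted into slices along z.
#'
#' @param object A [spatial_assignment()].
#' @param point_size Point size.
#' @param slices Number of z facets for 3-D assignments.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spatial_assignment
#' @export
autoplot.spatial_assignment <- function(object, point_size = 0.8,
                                        slices = 4L, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        colour = .data$population)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "population") +
    ggplot2::theme_minimal()
  if ("z" %in% names(df)) {
    df$slice <- cut(df$z, breaks = slices)
    p <- p %+% df + ggplot2::facet_wrap(~slice)
  }
  p
}

`%+%` <- ggplot2::`%+%`

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spot compositions
#'
#' Pie-free composition overview: spots positioned at their coordinates,
#' colored by majority population and sized by cell count.
#'
#' @param object A `spot_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spot_dataset
#' @export
autoplot.spot_dataset <- function(object, ...) {
  major <- colnames(object$composition)[max.col(object$composition,
                                                ties.method = "first")]
  df <- dplyr::mutate(object$spots, majority = major)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$majority,
                                   size = .data$n_cells)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(colour = "majority population", size = "cells") +
    ggplot2::theme_minimal()
}

#' Plot the spatial expression pattern of one gene
#'
#' @param assign A [spatial_assignment()].
#' @param expr An [expression_dataset()] aligned on cell ids.
#' @param gene Gene name.
#' @return A ggplot object.
#' @export
plot_gene_pattern <- function(assign, expr, gene) {
  idx <- match(assign$cell_id, expr$cell_ids)
  df <- tibble::tibble(x = assign$x, y = assign$y,
                       value = expr$matrix[idx, gene])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = gene) +
    ggplot2::theme_minimal()
}

#' Plot the VAE training loss trace
#'
#' @param model A trained `srt_vae`.
#' @return A ggplot object.
#' @export
plot_training_loss <- function(model) {
  df <- tibble::tibble(epoch = seq_along(model$epoch_loss),
                       loss = model$epoch_loss)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "mean batch loss (recon + KL)") +
    ggplot2::theme_minimal()
}
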