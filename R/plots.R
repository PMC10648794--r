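## ggplot2 displays for the main result types.

#' Plot training history
#'
#' Loss (and validation loss, when present) against epoch.
#'
#' @param object A `kc_history` tibble (the `history` element of a trained
#'   model or extractor).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kc_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[intersect(names(object), c("epoch", "loss", "val_loss"))],
    -"epoch",
    names_to = "series", values_to = "loss"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `kc_roc` tibble from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kc_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate") +
    ggplot2::theme_minimal()
}

#' Plot ReliefF feature weights
#'
#' Weights in rank order, highlighting the selected subset.
#'
#' @param object A `kc_relieff`.
#' @param n_selected Optionally mark the top-n cut.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kc_relieff <- function(object, n_selected = NULL, ...) {
  d <- dplyr::arrange(tidy(object), .data$rank)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$weight)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "feature rank", y = "ReliefF weight") +
    ggplot2::theme_minimal()
  if (!is.null(n_selected)) {
    p <- p + ggplot2::geom_vline(xintercept = n_selected + 0.5, linetype = 2)
  }
  p
}

#' Map tile QC status or predictions across a slide grid
#'
#' @param records Tile records from [tile_slide()], optionally joined with
#'   predictions.
#' @param fill Column to colour cells by (default `qc_status`).
#' @return A ggplot object with one cell per tile.
#' @export
plot_tile_map <- function(records, fill = "qc_status") {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$col, y = -.data$row,
    fill = .data[[fill]]
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "tile column", y = "tile row", fill = fill) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
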