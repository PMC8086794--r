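#' Plot a segmentation result
#'
#' Renders the three analysis compartments — vessel (hole-filled object
#' class), perivascular buffer, extravascular parenchyma — with the
#' thresholded IgG mask on top, in the conventional overlay colors (vessel
#' red, parenchyma blue, IgG yellow).
#'
#' @param object A `segmentation_result` from [analyze_image] or
#'   [quantify_classmap].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmentation_result <- function(object, ...) {
  cls <- matrix("buffer", nrow(object$vessel_mask), ncol(object$vessel_mask))
  cls[object$extravascular_mask] <- "parenchyma"
  cls[object$vessel_mask] <- "vessel"
  cls[object$igg_mask] <- "parenchymal IgG"
  df <- tibble(
    row = rep(seq_len(nrow(cls)), times = ncol(cls)),
    col = rep(seq_len(ncol(cls)), each = nrow(cls)),
    class = factor(as.vector(cls),
                   levels = c("vessel", "buffer", "parenchyma",
                              "parenchymal IgG")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      vessel = "#d62728", buffer = "grey30",
      parenchyma = "#1f77b4", `parenchymal IgG` = "#ffdf00")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' @export
plot.segmentation_result <- function(x, ...) print(autoplot.segmentation_result(x, ...))

#' Plot a per-image reproducibility table
#'
#' Takes a tibble with one row per image and one column per trial of
#' `igg_intensity_sum` (as produced by repeated [batch_analyze] runs bound
#' together) and shows trial-to-trial spread per image.
#'
#' @param records Tibble with columns `image_name`, `trial`,
#'   `igg_intensity_sum`.
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(records) {
  stopifnot(all(c("image_name", "trial", "igg_intensity_sum")
                %in% names(records)))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$image_name,
                               y = .data$igg_intensity_sum,
                               color = factor(.data$trial))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "image", y = "extravascular IgG intensity sum",
                  color = "trial") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
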