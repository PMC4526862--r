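#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an image slice with optional contour overlays
#'
#' @param image Numeric matrix (rows = y).
#' @param boundaries A [closed_boundary()] or list of them to overlay.
#' @param labels Optional legend labels for the overlaid contours.
#' @return A ggplot object (raster image, y axis pointing down as displayed).
#' @export
plot_slice <- function(image, boundaries = NULL, labels = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(image)) - 1,
                           x = seq_len(ncol(image)) - 1)
  df$intensity <- as.vector(t(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    if (inherits(boundaries, "closed_boundary")) boundaries <- list(boundaries)
    if (is.null(labels)) labels <- paste("contour", seq_along(boundaries))
    cdf <- purrr::map2(boundaries, labels, function(b, lab) {
      tibble::tibble(x = c(b$x, b$x[1]), y = c(b$y, b$y[1]), contour = lab)
    }) |> dplyr::bind_rows()
    p <- p + ggplot2::geom_path(
      data = cdf, ggplot2::aes(colour = .data$contour), linewidth = 0.6)
  }
  p
}

#' Plot all contours of a reconstructed surface
#'
#' @param object A `surface_model`.
#' @param ... Unused.
#' @return A ggplot object: contours coloured by slice index.
#' @export
autoplot.surface_model <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(df, dplyr::slice_head(dplyr::group_by(df, .data$z), n = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$z, colour = .data$z)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "slice") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of an offset solution
#'
#' Converged offsets against element index, with the convergence residual
#' trace inset-free alongside.
#'
#' @param object An `offset_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.offset_solution <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$element, y = .data$offset)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "boundary element", y = "offset (px, + outward)") +
    ggplot2::theme_minimal()
}
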