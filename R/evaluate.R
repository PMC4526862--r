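#' Rasterize a closed boundary to a binary mask
#'
#' A pixel belongs to the mask when its center (integer 0-based coordinates)
#' lies inside the polygon under the even-odd rule. Scanline implementation:
#' for each pixel row the x-crossings of all edges are collected and a pixel
#' is inside when an odd number of crossings lies strictly to its right.
#' Deterministic; matches the pixelwise region comparison used for
#' recall/precision.
#'
#' @param boundary A [closed_boundary()] (or data frame with `x`, `y`).
#' @param height,width Mask dimensions in pixels.
#' @return A logical height x width matrix (rows = y).
#' @export
rasterize_boundary <- function(boundary, height, width) {
  b <- as_boundary(boundary, check = FALSE)
  x1 <- b$x; y1 <- b$y
  n <- length(x1)
  if (n < 3 || abs(polygon_area(x1, y1)) == 0) {
    if (n < 3) stop("degenerate polygon: fewer than 3 vertices", call. = FALSE)
  }
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  mask <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    yc <- row - 1
    hit <- (y1 > yc) != (y2 > yc)
    if (!any(hit)) next
    xc <- x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    xc <- sort(xc)
    # pixel x inside iff #{crossings > x} is odd <=> #{crossings <= x} has
    # opposite parity to the total count
    cnt_le <- findInterval(seq_len(width) - 1, xc)
    mask[row, ] <- ((length(xc) - cnt_le) %% 2) == 1
  }
  mask
}

#' Overlap recall and precision between two closed boundaries
#'
#' Both boundaries are rasterized on the same pixel grid; `recall` is the
#' overlap area divided by the reference area (the gold standard — manual
#' tracing or ground truth), `precision` is the overlap area divided by the
#' test (reconstructed) area. Areas are pixel counts.
#'
#' @param reference The gold-standard [closed_boundary()].
#' @param test The boundary under evaluation.
#' @param height,width Grid dimensions in pixels.
#' @return A one-row tibble: `recall`, `precision`, `overlap_area`,
#'   `area_reference`, `area_test`.
#' @export
recall_precision <- function(reference, test, height, width) {
  mref <- rasterize_boundary(reference, height, width)
  mtest <- rasterize_boundary(test, height, width)
  a_ref <- sum(mref)
  a_test <- sum(mtest)
  if (a_ref == 0 || a_test == 0) {
    stop("undefined score: zero-area region after rasterization", call. = FALSE)
  }
  ov <- sum(mref & mtest)
  tibble::tibble(recall = ov / a_ref, precision = ov / a_test,
                 overlap_area = ov, area_reference = a_ref, area_test = a_test)
}

#' Per-slice overlap scores of a reconstructed surface
#'
#' Compares every contour of a [reconstruct_stack()] result against the
#' corresponding reference boundary.
#'
#' @param model A `surface_model`.
#' @param references List of gold-standard boundaries, same length/order as
#'   `model$boundaries`.
#' @param height,width Grid dimensions in pixels.
#' @return A tibble with one row per slice (`z`, `recall`, `precision`,
#'   areas).
#' @export
evaluate_surface <- function(model, references, height, width) {
  stopifnot(inherits(model, "surface_model"),
            length(references) == length(model$boundaries))
  purrr::map2(seq_along(references), references, function(i, ref) {
    dplyr::mutate(
      recall_precision(ref, model$boundaries[[i]], height, width),
      z = model$z_range[1] + i - 1L, .before = 1)
  }) |> dplyr::bind_rows()
}
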