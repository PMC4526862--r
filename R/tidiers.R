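#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an offset solution
#'
#' One row per boundary element: the converged signed offset (pixels; positive
#' is outward) and the per-element external weight.
#'
#' @param x An `offset_solution` from [evolve_offsets()].
#' @param ... Unused.
#' @return A tibble with columns `element`, `offset`, `beta`.
#' @export
tidy.offset_solution <- function(x, ...) {
  tibble::tibble(element = seq_along(x$offsets), offset = x$offsets,
                 beta = x$beta)
}

#' @rdname tidy.offset_solution
#' @return `glance()`: a one-row tibble with `n_elements`, `iterations`,
#'   `converged`, `final_residual`, `max_abs_offset`.
#' @export
glance.offset_solution <- function(x, ...) {
  tibble::tibble(
    n_elements = length(x$offsets),
    iterations = x$iterations,
    converged = x$converged,
    final_residual = if (length(x$residual_history)) utils::tail(x$residual_history, 1) else NA_real_,
    max_abs_offset = max(abs(x$offsets)))
}

#' Tidy a reconstructed surface
#'
#' One row per contour vertex across all slices.
#'
#' @param x A `surface_model` from [reconstruct_stack()].
#' @param ... Unused.
#' @return A tibble with columns `z`, `element`, `x`, `y`.
#' @export
tidy.surface_model <- function(x, ...) {
  purrr::imap(x$boundaries, function(b, i) {
    tibble::tibble(z = x$z_range[1] + i - 1L, element = seq_len(nrow(b)),
                   x = b$x, y = b$y)
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.surface_model
#' @return `glance()`: a one-row tibble with `n_slices`, `n_points`,
#'   `n_failed`, `n_converged`, `mean_iterations`.
#' @export
glance.surface_model <- function(x, ...) {
  tibble::tibble(
    n_slices = length(x$boundaries),
    n_points = nrow(x$boundaries[[1]]),
    n_failed = sum(x$per_slice$failed, na.rm = TRUE),
    n_converged = sum(x$per_slice$converged, na.rm = TRUE),
    mean_iterations = mean(x$per_slice$iterations, na.rm = TRUE))
}
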