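#' Refine one slice's boundary
#'
#' Runs the full per-slice chain: resample the initial boundary to `n_points`,
#' estimate exterior normals, resample image intensities along the normal
#' rays, condition the profiles (clamp, smooth, valid gradient), evolve the
#' offsets by the variational flow, and map the converged offsets back to a
#' closed contour (re-resampled to `n_points` so spacing stays uniform for the
#' next slice).
#'
#' @param image Numeric matrix of nonnegative intensities (rows = y).
#' @param init_boundary Initial [closed_boundary()] for this slice, e.g. the
#'   refined boundary of the neighbouring slice.
#' @param params A [solver_params()].
#' @return The refined `closed_boundary`, with the `offset_solution` attached
#'   as attribute `"solution"`.
#' @export
reconstruct_slice <- function(image, init_boundary, params = solver_params()) {
  b0 <- resample_closed_polyline(init_boundary, params$n_points)
  normals <- exterior_normals(b0)
  rays <- sample_ray_signals(image, b0, normals, params$M)
  rays <- condition_rays(rays, smoothing_passes = params$smoothing_passes)
  sol <- evolve_offsets(rays, params)
  out <- boundary_from_offsets(b0, normals, sol)
  if (any(sol$offsets != 0)) {
    out <- resample_closed_polyline(out, params$n_points)
  }
  attr(out, "solution") <- sol
  out
}

#' Reconstruct a surface from an image stack
#'
#' Propagates boundary refinement through the stack: the refined boundary of
#' slice z is used as the initial boundary for slice z+1 (and/or z-1 when
#' running backward). The z-ordered refined contours form the reconstructed
#' surface. A slice whose refinement fails (self-intersection beyond repair,
#' rays leaving the image) reuses the previous slice's boundary and is
#' flagged, so one bad slice does not end a long run.
#'
#' @param stack A 3D array (rows x cols x slices) or list of equally sized
#'   matrices.
#' @param init_boundary The user-supplied [closed_boundary()] for slice
#'   `start_z`.
#' @param params A [solver_params()].
#' @param start_z Index (1-based) of the slice the initial boundary belongs to.
#' @param direction One of `"forward"`, `"backward"`, `"both"`.
#' @param voxel_size Physical voxel size per axis, e.g. `c(2, 2, 2)` microns.
#' @return A `surface_model`: list with `boundaries` (one per processed
#'   slice, in z order), `voxel_size`, `z_range` and a `per_slice` diagnostics
#'   tibble (`z`, `iterations`, `residual`, `converged`, `failed`).
#' @export
reconstruct_stack <- function(stack, init_boundary, params = solver_params(),
                              start_z = 1, direction = c("forward", "backward", "both"),
                              voxel_size = c(2, 2, 2)) {
  direction <- match.arg(direction)
  slices <- as_slice_list(stack)
  nz <- length(slices)
  if (nz == 0) stop("empty stack", call. = FALSE)
  stopifnot(start_z >= 1, start_z <= nz)

  boundaries <- vector("list", nz)
  diag_rows <- vector("list", nz)

  run_one <- function(z, init_b) {
    res <- tryCatch(reconstruct_slice(slices[[z]], init_b, params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("slice %d failed (%s); reusing previous boundary",
                      z, conditionMessage(res)), call. = FALSE)
      b <- resample_closed_polyline(init_b, params$n_points)
      diag_rows[[z]] <<- tibble::tibble(z = z, iterations = NA_integer_,
                                        residual = NA_real_, converged = FALSE,
                                        failed = TRUE)
      boundaries[[z]] <<- b
      return(b)
    }
    sol <- attr(res, "solution")
    diag_rows[[z]] <<- tibble::tibble(
      z = z, iterations = sol$iterations,
      residual = if (length(sol$residual_history)) utils::tail(sol$residual_history, 1) else 0,
      converged = sol$converged, failed = FALSE)
    attr(res, "solution") <- NULL
    boundaries[[z]] <<- res
    res
  }

  zs_fwd <- if (direction %in% c("forward", "both")) seq(start_z, nz) else start_z
  b <- init_boundary
  for (z in zs_fwd) b <- run_one(z, b)
  if (direction %in% c("backward", "both") && start_z > 1) {
    b <- boundaries[[start_z]]
    for (z in seq(start_z - 1, 1)) b <- run_one(z, b)
  }

  keep <- !vapply(boundaries, is.null, logical(1))
  structure(list(
    boundaries = boundaries[keep],
    voxel_size = voxel_size,
    z_range = range(which(keep)),
    per_slice = dplyr::bind_rows(diag_rows[keep])
  ), class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d slices (z %d..%d), %d points/contour, %d failed\n",
              length(x$boundaries), x$z_range[1], x$z_range[2],
              nrow(x$boundaries[[1]]), sum(x$per_slice$failed)))
  invisible(x)
}

# normalise stacks: 3D array or list of matrices -> list of matrices
as_slice_list <- function(stack) {
  if (is.list(stack)) {
    stopifnot(all(vapply(stack, is.matrix, logical(1))))
    dims <- vapply(stack, dim, integer(2))
    if (length(stack) > 1 && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
      stop("slices have mixed shapes", call. = FALSE)
    }
    return(stack)
  }
  if (is.array(stack) && length(dim(stack)) == 3) {
    return(lapply(seq_len(dim(stack)[3]), function(z) stack[, , z]))
  }
  if (is.matrix(stack)) return(list(stack))
  stop("`stack` must be a 3D array or a list of matrices", call. = FALSE)
}
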