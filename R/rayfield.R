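#' Sample image intensities along boundary-normal rays
#'
#' For every boundary element i, positions `p_{m,i} = origin_i + m * n_i` are
#' taken at integer offsets `m = -M .. M` along the exterior normal (negative
#' m is interior, positive m exterior). The signal `v(p_{m,i})` is the mean
#' intensity of the 5x5 pixel window centered on the pixel containing the
#' position (windows clipped at image borders average in-image pixels only).
#' These rays and signals — the resampling dataset — are the only part of the
#' image the boundary solver ever reads, which is what keeps the method local.
#'
#' Pixel centers sit at integer 0-based coordinates (`x` = column, `y` = row);
#' the containing pixel of a position is nearest-integer rounding with ties
#' toward +Inf.
#'
#' @param image Numeric matrix of nonnegative intensities (rows = y, cols = x).
#' @param boundary A [closed_boundary()] giving the ray origins.
#' @param normals N x 2 matrix of unit exterior normals (see
#'   [exterior_normals()]).
#' @param M Half-width of the offset range in pixels (>= 2).
#' @return A `ray_field` object: list with `origins`, `normals`, `M`,
#'   `offsets`, `raw_signal` (N x (2M+1)); conditioning fields are filled in
#'   by [condition_rays()].
#' @export
sample_ray_signals <- function(image, boundary, normals, M) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.numeric(M) || length(M) != 1 || M < 2) {
    stop("`M` must be a single integer >= 2", call. = FALSE)
  }
  M <- as.integer(M)
  b <- as_boundary(boundary, check = FALSE)
  n <- nrow(b)
  stopifnot(nrow(normals) == n)
  h <- nrow(image); w <- ncol(image)

  offs <- seq.int(-M, M)
  # N x (2M+1) position grids
  px <- outer(b$x, offs, function(x0, m) x0) + outer(normals[, 1], offs)
  py <- outer(b$y, offs, function(y0, m) y0) + outer(normals[, 2], offs)
  # containing pixel: round half up, 0-based
  cx <- floor(px + 0.5)
  cy <- floor(py + 0.5)

  bad <- cx < 0 | cx > w - 1 | cy < 0 | cy > h - 1
  if (any(bad)) {
    el <- which(rowSums(bad) > 0)[1]
    stop(sprintf(
      "ray for boundary element %d leaves the image (%d x %d); reduce M or move the boundary",
      el, h, w), call. = FALSE)
  }

  # 25-pixel window mean, accumulated in a fixed pixel order so the result is
  # bit-reproducible under integer translation of image + boundary
  acc <- matrix(0, n, 2L * M + 1L)
  cnt <- matrix(0L, n, 2L * M + 1L)
  for (dr in -2:2) {
    for (dc in -2:2) {
      rr <- cy + dr
      cc <- cx + dc
      ok <- rr >= 0 & rr <= h - 1 & cc >= 0 & cc <= w - 1
      idx <- (cc[ok]) * h + rr[ok] + 1  # column-major linear index, 1-based
      acc[ok] <- acc[ok] + image[idx]
      cnt[ok] <- cnt[ok] + 1L
    }
  }
  raw <- acc / cnt

  structure(list(
    origins = cbind(x = b$x, y = b$y),
    normals = normals,
    M = M,
    offsets = offs,
    raw_signal = raw,
    conditioned_signal = NULL,
    grad = NULL,
    L1 = NULL,
    L2 = NULL
  ), class = "ray_field")
}

#' @export
print.ray_field <- function(x, ...) {
  cat(sprintf("<ray_field> %d rays, M = %d%s\n", nrow(x$raw_signal), x$M,
              if (is.null(x$grad)) " (unconditioned)" else ""))
  invisible(x)
}

#' Clamp a ray profile to its interior/exterior mean band
#'
#' Extreme values along one ray are suppressed by constraining the signal to
#' the interval spanned by `L1`, the mean over the exterior samples
#' (m = 1..M), and `L2`, the mean over the interior samples (m = -M..-1).
#' With a bright interior, L1 < L2 and the clamp caps bright interference
#' outside the boundary at the interior level while leaving the boundary
#' transition untouched. The m = 0 sample is clamped like the rest but is
#' excluded from both averages.
#'
#' @param ray_signal Numeric vector of length 2M+1 (offsets -M..M), or an
#'   N x (2M+1) matrix of such profiles (one per row).
#' @param L1,L2 Optional fixed clamp bounds (per ray). By default they are
#'   computed from the profile itself; once computed for a resampling dataset
#'   they are held fixed, so re-clamping with the same bounds is a no-op.
#' @return A list with `clamped` (same shape as the input), `L1` and `L2`
#'   (one value per ray).
#' @export
clamp_profile <- function(ray_signal, L1 = NULL, L2 = NULL) {
  v <- if (is.matrix(ray_signal)) ray_signal else matrix(ray_signal, nrow = 1)
  if (ncol(v) < 5 || ncol(v) %% 2 == 0) {
    stop("profile length must be odd (2M+1) with M >= 2", call. = FALSE)
  }
  M <- (ncol(v) - 1L) %/% 2L
  if (is.null(L2)) L2 <- rowMeans(v[, seq_len(M), drop = FALSE])          # m = -M..-1 (interior)
  if (is.null(L1)) L1 <- rowMeans(v[, M + 1L + seq_len(M), drop = FALSE]) # m = 1..M (exterior)
  lo <- pmin(L1, L2)
  hi <- pmax(L1, L2)
  clamped <- pmin(pmax(v, lo), hi)
  if (!is.matrix(ray_signal)) clamped <- clamped[1, ]
  list(clamped = clamped, L1 = L1, L2 = L2)
}

#' Smooth a signal with the repeated 3-point mean
#'
#' Each pass replaces every sample by the mean of itself and its two
#' neighbours; endpoints use edge replication (a virtual sample equal to the
#' end value), which preserves constant signals. The default ten passes match
#' the conditioning used for the ray profiles.
#'
#' @param signal Numeric vector (length >= 3) or matrix (profiles in rows).
#' @param passes Number of smoothing passes (positive integer).
#' @return Smoothed signal, same shape and length as the input.
#' @export
smooth_profile <- function(signal, passes = 10) {
  stopifnot(passes >= 1)
  v <- if (is.matrix(signal)) signal else matrix(signal, nrow = 1)
  k <- ncol(v)
  if (k < 3) stop("signal must have length >= 3", call. = FALSE)
  for (p in seq_len(passes)) {
    left <- v[, c(1L, seq_len(k - 1L)), drop = FALSE]
    right <- v[, c(seq_len(k)[-1], k), drop = FALSE]
    v <- (left + v + right) / 3
  }
  if (!is.matrix(signal)) v <- v[1, ]
  v
}

#' Valid gradient of a conditioned ray profile
#'
#' The forward difference of the smoothed profile is negated and thresholded
#' at zero: `g_m = max(0, v(p_m) - v(p_{m+1}))` for m = -M..M-1. Because the
#' interior is brighter than the exterior, the true boundary shows up as a
#' positive peak of g (intensity dropping outward); rising stretches carry no
#' boundary evidence and are zeroed.
#'
#' @param smoothed_signal Numeric vector of length 2M+1, or N x (2M+1) matrix.
#' @return Vector of length 2M (or N x 2M matrix), all values >= 0. Sample m
#'   of the output lives at ray offset m + 1/2 (the midpoint of the
#'   difference).
#' @export
valid_gradient <- function(smoothed_signal) {
  v <- if (is.matrix(smoothed_signal)) smoothed_signal else matrix(smoothed_signal, nrow = 1)
  k <- ncol(v)
  d <- v[, seq_len(k)[-1], drop = FALSE] - v[, seq_len(k - 1L), drop = FALSE]
  g <- pmax(-d, 0)
  if (!is.matrix(smoothed_signal)) g <- g[1, ]
  g
}

#' Run the full signal-conditioning chain on a ray field
#'
#' Applies [clamp_profile()], [smooth_profile()] and [valid_gradient()] to the
#' raw signals of every ray, filling the `conditioned_signal`, `grad`, `L1`
#' and `L2` fields.
#'
#' @param rays A `ray_field` from [sample_ray_signals()].
#' @param smoothing_passes Number of 3-point smoothing passes (default 10).
#' @return The completed `ray_field`.
#' @export
condition_rays <- function(rays, smoothing_passes = 10) {
  stopifnot(inherits(rays, "ray_field"))
  cl <- clamp_profile(rays$raw_signal)
  sm <- smooth_profile(cl$clamped, passes = smoothing_passes)
  rays$conditioned_signal <- sm
  rays$grad <- valid_gradient(sm)
  rays$L1 <- cl$L1
  rays$L2 <- cl$L2
  rays
}
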