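#' Specify a synthetic phantom stack
#'
#' Describes a star-convex object whose radius varies with angle,
#' `rho(theta) = base_radius * (1 + sum_j a_j cos(j theta + phi_j))`, drifting
#' slowly across slices (`z_drift` radial scale factor per slice). The
#' rendered images emulate the imaging regime the boundary model targets:
#' interior brighter than exterior, strong low-frequency multiplicative
#' inhomogeneity of the interior intensity, optional bright interference
#' blobs just outside the boundary, and additive Gaussian noise. Intensities
#' are rounded to integer counts (as a detector produces) and clipped at 0.
#'
#' @param width,height,n_slices Image and stack dimensions (pixels/slices).
#' @param base_radius Mean radius in pixels.
#' @param harmonics Data frame (or list of `c(order, amplitude, phase)`) with
#'   columns `order`, `amplitude`, `phase`; `sum(|amplitude|) < 0.5` keeps the
#'   shape star-convex and simple.
#' @param z_drift Per-slice radial scale factor (1 = constant shape).
#' @param intensity_in,intensity_out Mean interior/exterior intensities;
#'   `intensity_in > intensity_out >= 0`.
#' @param inhomogeneity_amp Relative amplitude of the low-frequency
#'   (angular + axial) multiplicative field on the interior, in [0, 1).
#' @param blobs Data frame with columns `theta`, `width` (radians), `offset`
#'   (px outside the local boundary), `intensity`, `z_from`, `z_to` (1-based,
#'   inclusive) and optionally `thickness` (radial extent, default 4 px);
#'   `NULL` for none.
#' @param noise_sd Additive zero-mean Gaussian noise scale (>= 0).
#' @param seed RNG seed; the rendered stack is fully determined by it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 220, height = 220, n_slices = 20,
                         base_radius = 60,
                         harmonics = data.frame(order = integer(0),
                                                amplitude = numeric(0),
                                                phase = numeric(0)),
                         z_drift = 1, intensity_in = 120, intensity_out = 20,
                         inhomogeneity_amp = 0, blobs = NULL, noise_sd = 0,
                         seed = 0) {
  if (is.list(harmonics) && !is.data.frame(harmonics)) {
    harmonics <- do.call(rbind, lapply(harmonics, function(h) {
      data.frame(order = h[1], amplitude = h[2], phase = h[3])
    }))
  }
  stopifnot(width >= 8, height >= 8, n_slices >= 1, base_radius > 0,
            z_drift > 0, inhomogeneity_amp >= 0, inhomogeneity_amp < 1,
            noise_sd >= 0)
  if (intensity_in <= intensity_out || intensity_out < 0) {
    stop("need intensity_in > intensity_out >= 0 (bright interior)", call. = FALSE)
  }
  if (nrow(harmonics) && sum(abs(harmonics$amplitude)) >= 0.5) {
    stop("sum of |harmonic amplitudes| must be < 0.5 (star-convex shape)",
         call. = FALSE)
  }
  if (intensity_in * (1 - inhomogeneity_amp) <= intensity_out) {
    stop("inhomogeneity would make the interior darker than the exterior",
         call. = FALSE)
  }
  if (!is.null(blobs)) {
    blobs <- as.data.frame(blobs)
    if (is.null(blobs$thickness)) blobs$thickness <- 4
  }
  structure(list(width = width, height = height, n_slices = n_slices,
                 base_radius = base_radius, harmonics = harmonics,
                 z_drift = z_drift, intensity_in = intensity_in,
                 intensity_out = intensity_out,
                 inhomogeneity_amp = inhomogeneity_amp, blobs = blobs,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

#' The standard test phantom
#'
#' A 220 x 220 x 20 stack: three- and five-lobed star-convex shape
#' (harmonics (3, 0.12, 0) and (5, 0.05, 1.0)) of base radius 60 px growing
#' by a factor 1.003 per slice, interior/exterior intensities 120/20, 30%
#' interior inhomogeneity, one exterior interference blob (centre pi/4, arc
#' width 20 degrees, 5 px outside the boundary, intensity 110, slices 9-13),
#' Gaussian noise sd 6, seed 0.
#'
#' @param blob Include the interference blob (default `TRUE`).
#' @return A [phantom_spec()].
#' @export
standard_phantom_spec <- function(blob = TRUE) {
  phantom_spec(
    width = 220, height = 220, n_slices = 20, base_radius = 60,
    harmonics = data.frame(order = c(3, 5), amplitude = c(0.12, 0.05),
                           phase = c(0, 1.0)),
    z_drift = 1.003, intensity_in = 120, intensity_out = 20,
    inhomogeneity_amp = 0.3,
    blobs = if (blob) data.frame(theta = pi / 4, width = 20 * pi / 180,
                                 offset = 5, intensity = 110,
                                 z_from = 9, z_to = 13) else NULL,
    noise_sd = 6, seed = 0)
}

phantom_center <- function(spec) c((spec$width - 1) / 2, (spec$height - 1) / 2)

phantom_radius <- function(spec, theta, z) {
  rho <- rep(1, length(theta))
  h <- spec$harmonics
  if (!is.null(h) && nrow(h)) {
    for (i in seq_len(nrow(h))) {
      rho <- rho + h$amplitude[i] * cos(h$order[i] * theta + h$phase[i])
    }
  }
  spec$base_radius * rho * spec$z_drift^(z - 1)
}

#' Ground-truth boundary of a phantom slice
#'
#' Samples the star-convex radius function at `n_points` equally spaced
#' angles, scaled by the per-slice drift, centred in the image. CCW order.
#'
#' @param spec A [phantom_spec()].
#' @param z Slice index (1-based).
#' @param n_points Number of polygon vertices.
#' @return A [closed_boundary()].
#' @export
truth_boundary <- function(spec, z, n_points = 720) {
  stopifnot(inherits(spec, "phantom_spec"), z >= 1, z <= spec$n_slices)
  theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
  rho <- phantom_radius(spec, theta, z)
  ctr <- phantom_center(spec)
  if (max(rho) > min(ctr) - 2) {
    stop("phantom shape exceeds the image margins", call. = FALSE)
  }
  closed_boundary(tibble::tibble(x = ctr[1] + rho * cos(theta),
                                 y = ctr[2] + rho * sin(theta)),
                  check = FALSE)
}

#' Render a phantom stack with known ground truth
#'
#' Rasterises the truth shape of every slice (pixel-center-in-polygon,
#' even-odd rule), fills the interior with `intensity_in` modulated by the
#' low-frequency inhomogeneity field `1 + amp * sin(theta + 0.25 z)` and the
#' exterior with `intensity_out`, paints the interference blobs as bright arc
#' bands outside the boundary, adds Gaussian noise, clips at zero and rounds
#' to integer counts. The RNG state is fully determined by `spec$seed` (the
#' caller's RNG state is restored afterwards).
#'
#' @param spec A [phantom_spec()].
#' @param truth_points Vertices per returned truth boundary.
#' @return List with `stack` (height x width x n_slices array) and `truths`
#'   (list of [closed_boundary()], one per slice).
#' @export
generate_phantom <- function(spec, truth_points = 720) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  ctr <- phantom_center(spec)
  # pixel-center coordinate grids (0-based)
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1, h, w)
  theta_p <- atan2(ys - ctr[2], xs - ctr[1])
  rad_p <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  stack <- array(0, dim = c(h, w, spec$n_slices))
  truths <- vector("list", spec$n_slices)
  for (z in seq_len(spec$n_slices)) {
    tb <- truth_boundary(spec, z, n_points = truth_points)
    truths[[z]] <- tb
    inside <- rasterize_boundary(tb, height = h, width = w)
    field <- 1 + spec$inhomogeneity_amp * sin(theta_p + 0.25 * (z - 1))
    img <- ifelse(inside, spec$intensity_in * field, spec$intensity_out)
    if (!is.null(spec$blobs)) {
      for (bi in seq_len(nrow(spec$blobs))) {
        bl <- spec$blobs[bi, ]
        if (z < bl$z_from || z > bl$z_to) next
        dthe <- atan2(sin(theta_p - bl$theta), cos(theta_p - bl$theta))
        rho_b <- phantom_radius(spec, theta_p, z)
        hit <- abs(dthe) <= bl$width / 2 &
          rad_p >= rho_b + bl$offset &
          rad_p <= rho_b + bl$offset + bl$thickness
        img[hit] <- pmax(img[hit], bl$intensity)
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    }
    stack[, , z] <- round(pmax(img, 0))
  }
  list(stack = stack, truths = truths)
}
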