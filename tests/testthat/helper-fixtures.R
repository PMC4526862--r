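# Shared fixtures, built in code at test time.

# regular n-gon on a circle (CCW)
circle_boundary <- function(radius, center = c(0, 0), n = 360) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  closed_boundary(tibble::tibble(x = center[1] + radius * cos(th),
                                 y = center[2] + radius * sin(th)),
                  check = FALSE)
}

# uniform bright disc on a dark background; pixel centers at 0-based ints
disc_image <- function(size = 200, radius = 60, center = (size - 1) / 2,
                       inside = 120, outside = 20) {
  xs <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  ys <- matrix(seq_len(size) - 1, size, size)
  ifelse((xs - center)^2 + (ys - center)^2 <= radius^2, inside, outside)
}

# conditioned valid-gradient profile of a synthetic single-edge ray:
# bright interior, dark exterior, edge at a random sub-pixel offset
random_edge_gradient <- function(M = 30, edge = runif(1, -8, 8),
                                 inn = runif(1, 60, 160),
                                 out = runif(1, 5, 30), noise_sd = 5) {
  m <- seq(-M, M)
  v <- ifelse(m < edge, inn, out) + rnorm(2 * M + 1, sd = noise_sd)
  valid_gradient(smooth_profile(clamp_profile(v)$clamped, 10))
}

# a ray_field carrying prescribed gradient rows (solver only reads grad + M)
gradient_ray_field <- function(G, M) {
  n <- nrow(G)
  th <- 2 * pi * (seq_len(n) - 1) / n
  structure(list(origins = cbind(x = 100 + 50 * cos(th), y = 100 + 50 * sin(th)),
                 normals = cbind(nx = cos(th), ny = sin(th)),
                 M = as.integer(M), offsets = seq.int(-M, M),
                 raw_signal = NULL, conditioned_signal = NULL,
                 grad = G, L1 = NULL, L2 = NULL),
            class = "ray_field")
}

# signed radial error of each vertex relative to a circle
radial_errors <- function(boundary, center, radius) {
  sqrt((boundary$x - center[1])^2 + (boundary$y - center[2])^2) - radius
}

# brute-force even-odd point-in-polygon (independent of rasterize_boundary)
brute_mask <- function(boundary, height, width) {
  px <- boundary$x; py <- boundary$y
  n <- length(px)
  mask <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      x <- col - 1; y <- row - 1
      cross <- 0L
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        if ((py[i] > y) != (py[j] > y)) {
          xi <- px[i] + (y - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
          if (x < xi) cross <- cross + 1L
        }
      }
      mask[row, col] <- cross %% 2L == 1L
    }
  }
  mask
}
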