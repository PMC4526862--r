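# Boundary discretisation, normal estimation, ray resampling and the
# signal-conditioning chain.

test_that("arc-length resampling spaces points uniformly and hits hand-derived positions", {
  sq <- closed_boundary(tibble::tibble(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)),
                        check = FALSE)
  r8 <- resample_closed_polyline(sq, 8)
  # perimeter 8, spacing 1: corners plus edge midpoints, starting at (0,0)
  expect_equal(as.matrix(r8[, c("x", "y")]),
               cbind(x = c(0, 1, 2, 2, 2, 1, 0, 0),
                     y = c(0, 0, 0, 1, 2, 2, 2, 1)),
               ignore_attr = TRUE)
  # uniform arc-length spacing invariant (relative 1e-6) on a wiggly shape:
  # measure the polyline arc position of every output point independently
  wig <- circle_boundary(60, c(100, 100), 97)
  wig$x <- wig$x + 3 * sin(5 * seq_len(97))
  wig <- closed_boundary(wig, check = FALSE)
  r <- resample_closed_polyline(wig, 211)
  xs <- c(wig$x, wig$x[1]); ys <- c(wig$y, wig$y[1])
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum <- c(0, cumsum(seg))
  arc_pos <- vapply(seq_len(211), function(j) {
    # nearest segment and projection fraction of output point j
    d2 <- (xs[-length(xs)] - r$x[j])^2 + (ys[-length(ys)] - r$y[j])^2
    best <- Inf; pos <- NA_real_
    for (i in order(d2)[1:4]) {
      t <- ((r$x[j] - xs[i]) * (xs[i + 1] - xs[i]) +
            (r$y[j] - ys[i]) * (ys[i + 1] - ys[i])) / seg[i]^2
      t <- min(max(t, 0), 1)
      dd <- (xs[i] + t * (xs[i + 1] - xs[i]) - r$x[j])^2 +
            (ys[i] + t * (ys[i + 1] - ys[i]) - r$y[j])^2
      if (dd < best) { best <- dd; pos <- cum[i] + t * seg[i] }
    }
    pos
  }, numeric(1))
  targets <- cum[length(cum)] * (seq_len(211) - 1) / 211
  expect_lt(max(abs(arc_pos - targets)), 1e-6 * cum[length(cum)])
})

test_that("resampling an already-uniform boundary is an exact identity", {
  b <- circle_boundary(60, c(80, 80), 360)
  expect_identical(resample_closed_polyline(b, 360)$x, b$x)
  expect_identical(resample_closed_polyline(b, 360)$y, b$y)
})

test_that("resampling a dense polygon of a circle stays on the circle", {
  b <- circle_boundary(60, c(100, 100), 360)
  r <- resample_closed_polyline(b, 720)
  expect_lt(max(abs(radial_errors(r, c(100, 100), 60))), 0.01)
})

test_that("resampling rejects bad input", {
  bow <- tibble::tibble(x = c(0, 2, 0, 2, 0, 1, 2, 1), y = c(0, 2, 2, 0, 1, 3, 1, -1))
  expect_error(resample_closed_polyline(bow, 16), "self-intersect")
  sq <- closed_boundary(tibble::tibble(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)),
                        check = FALSE)
  expect_error(resample_closed_polyline(sq, 4), "n_points")
})

test_that("exterior normals of a regular CCW polygon are the outward radials", {
  b <- circle_boundary(50, c(10, -4), 64)
  nn <- exterior_normals(b)
  th <- 2 * pi * (seq_len(64) - 1) / 64
  expect_equal(nn[, 1], cos(th), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nn[, 2], sin(th), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sqrt(rowSums(nn^2)), rep(1, 64), tolerance = 1e-12)
})

test_that("unit-square normals bisect the corners and orientation is canonicalised", {
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  nn <- exterior_normals(closed_boundary(sq, check = FALSE))
  expect_equal(nn[2, ], c(1, -1) / sqrt(2), tolerance = 1e-12, ignore_attr = TRUE)
  # reversed (CW) vertex order canonicalises to the same normals
  rev_sq <- sq[c(1, 4, 3, 2), ]
  nn2 <- exterior_normals(closed_boundary(rev_sq, check = FALSE))
  expect_equal(nn2, nn)
  # degenerate: coincident neighbours
  bad <- tibble::tibble(x = c(0, 1, 0, 0.5, 1, 1, 0.5, 0),
                        y = c(0, 0, 0, 0.2, 0.5, 1, 1.2, 1))
  bad$x[3] <- bad$x[1]; bad$y[3] <- bad$y[1]  # chord i-1 -> i+1 collapses
  expect_error(exterior_normals(closed_boundary(bad, check = FALSE)),
               "degenerate")
})

test_that("normals of a CCW convex polygon point away from the centroid", {
  b <- circle_boundary(30, c(50, 50), 23)
  b$x <- b$x * 1.4  # ellipse, still convex
  b <- closed_boundary(b, check = FALSE)
  nn <- exterior_normals(b)
  d <- cbind(b$x - mean(b$x), b$y - mean(b$y))
  expect_true(all(rowSums(nn * d) > 0))
})

test_that("ray sampling averages the 5x5 window and flags out-of-image rays", {
  img <- matrix(7, 64, 64)
  b <- circle_boundary(15, c(31.5, 31.5), 24)
  rays <- sample_ray_signals(img, b, exterior_normals(b), M = 5)
  expect_true(all(rays$raw_signal == 7))
  expect_equal(dim(rays$raw_signal), c(24, 11))
  # step image: 10 for x in 0..49 (columns 1:50), 0 beyond
  stp <- matrix(0, 100, 100); stp[, 1:50] <- 10
  th <- 2 * pi * (0:35) / 36
  hb <- closed_boundary(
    tibble::tibble(x = 30 + 12 * cos(th), y = 50 + 12 * sin(th)), check = FALSE)
  nrm <- exterior_normals(hb)
  rays <- sample_ray_signals(stp, hb, nrm, M = 10)
  right <- which.max(nrm[, 1])  # ray along +x from (42, 50), crossing x = 49.5
  prof <- rays$raw_signal[right, ]
  expect_true(all(diff(prof) <= 0))             # monotone decrease across the step
  expect_equal(prof[1], 10); expect_equal(prof[21], 0)
  expect_lte(sum(diff(prof) < 0), 6)            # ~5-sample transition
  # window-average oracle at m = +8: position x = 50, 5x5 window cols 48..52
  expect_equal(prof[19], mean(stp[49:53, 49:53]), tolerance = 1e-12)
  # ray leaving the image names the element
  expect_error(sample_ray_signals(stp, hb, nrm, M = 40), "element")
})

test_that("profile clamping matches the hand-worked example and is idempotent", {
  out <- clamp_profile(c(10, 9, 5, 1, 0))
  expect_equal(out$L2, 9.5)
  expect_equal(out$L1, 0.5)
  expect_equal(out$clamped, c(9.5, 9, 5, 1, 0.5))
  # no-op when already inside the [L1, L2] band; constants are fixed points
  expect_equal(clamp_profile(c(8, 8, 5, 2, 2))$clamped, c(8, 8, 5, 2, 2))
  expect_equal(clamp_profile(rep(4, 9))$clamped, rep(4, 9))
  # idempotent under the per-ray bounds, which are fixed once computed
  set.seed(7)
  v <- runif(21, 0, 100)
  cl <- clamp_profile(v)
  expect_equal(clamp_profile(cl$clamped, L1 = cl$L1, L2 = cl$L2)$clamped,
               cl$clamped)
})

test_that("3-point smoothing replicates edges, preserves constants and lines", {
  expect_equal(smooth_profile(c(0, 3, 0), passes = 1), c(1, 1, 1))
  expect_equal(smooth_profile(rep(5, 11), passes = 25), rep(5, 11))
  ramp <- seq(0, 10, length.out = 11)
  expect_equal(smooth_profile(ramp, passes = 1)[2:10], ramp[2:10])
})

test_that("smoothing is a contraction in max-norm", {
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(31, sd = 10)
    s <- smooth_profile(v, passes = sample(1:12, 1))
    expect_lte(max(s), max(v))
    expect_gte(min(s), min(v))
  }
})

test_that("valid gradient keeps only intensity drops and conserves descent", {
  expect_equal(valid_gradient(c(8, 8, 8, 2, 2)), c(0, 0, 6, 0))
  expect_equal(valid_gradient(1:9), rep(0, 8))
  expect_equal(valid_gradient(rep(3, 9)), rep(0, 8))
  set.seed(3)
  for (i in 1:20) {
    v <- cumsum(rnorm(41))
    g <- valid_gradient(v)
    expect_true(all(g >= 0))
    d <- diff(v)
    expect_equal(sum(g), -sum(d[d < 0]))  # total negative variation
  }
})

test_that("a constant image yields an identically zero valid gradient", {
  img <- matrix(42, 80, 80)
  b <- circle_boundary(20, c(39.5, 39.5), 36)
  rays <- condition_rays(sample_ray_signals(img, b, exterior_normals(b), M = 8))
  expect_true(all(rays$grad == 0))
  expect_true(all(rays$conditioned_signal >= pmin(rays$L1, rays$L2) - 1e-12))
  expect_true(all(rays$conditioned_signal <= pmax(rays$L1, rays$L2) + 1e-12))
})
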