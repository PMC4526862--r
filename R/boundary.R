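#' Closed boundary contours
#'
#' A closed boundary is an ordered, cyclic list of planar points (continuous
#' pixel units, `x` = column, `y` = row, 0-based pixel centers) describing one
#' slice's contour. It is stored as a tibble with columns `x` and `y` and class
#' `closed_boundary`; the closing edge from the last point back to the first is
#' implied. Vertex order is canonicalised to counter-clockwise (positive
#' shoelace area).
#'
#' @param points A data frame (or matrix) with columns/two columns `x`, `y`.
#' @param check If `TRUE` (default), verify the polygon is simple
#'   (non-self-intersecting) and has at least 8 vertices.
#' @return A `closed_boundary` tibble with columns `x`, `y`.
#' @export
closed_boundary <- function(points, check = TRUE) {
  if (is.matrix(points)) {
    points <- tibble::tibble(x = points[, 1], y = points[, 2])
  }
  if (!all(c("x", "y") %in% names(points))) {
    stop("`points` must have columns `x` and `y`", call. = FALSE)
  }
  pts <- tibble::as_tibble(points[, c("x", "y")])
  if (!all(is.finite(pts$x)) || !all(is.finite(pts$y))) {
    stop("boundary coordinates must be finite", call. = FALSE)
  }
  # drop an explicit duplicate closing vertex
  n <- nrow(pts)
  if (n > 1 && pts$x[1] == pts$x[n] && pts$y[1] == pts$y[n]) {
    pts <- pts[-n, , drop = FALSE]
  }
  if (check) {
    if (nrow(pts) < 8) {
      stop("a closed boundary needs at least 8 points", call. = FALSE)
    }
    if (!is_simple_polygon(pts$x, pts$y)) {
      stop("invalid boundary: polygon is self-intersecting", call. = FALSE)
    }
  }
  pts <- ensure_ccw(pts)
  class(pts) <- c("closed_boundary", class(tibble::tibble()))
  pts
}

#' @export
print.closed_boundary <- function(x, ...) {
  cat(sprintf("<closed_boundary> %d points, area %.2f px^2\n",
              nrow(x), polygon_area(x$x, x$y)))
  NextMethod()
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param x,y Vertex coordinates (closing edge implied).
#' @return Signed area in squared pixel units.
#' @export
polygon_area <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# reorder vertices counter-clockwise, keeping the first vertex first
ensure_ccw <- function(pts) {
  if (polygon_area(pts$x, pts$y) < 0) {
    n <- nrow(pts)
    pts <- pts[c(1L, n:2L), , drop = FALSE]
  }
  pts
}

# Simplicity test: no two non-adjacent edges intersect. O(n^2) vectorised
# segment-pair orientation tests; adjacent edges (sharing a vertex) skipped.
is_simple_polygon <- function(x, y) {
  n <- length(x)
  if (n < 3) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  # degenerate zero-length edges
  if (any(x == x2 & y == y2)) return(FALSE)
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    # candidate edges j > i, non-adjacent (cyclically)
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]
    if (length(j) == 0L) next
    d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
    d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- cross(x[j], y[j], x2[j], y2[j], rep(x[i], length(j)), rep(y[i], length(j)))
    d4 <- cross(x[j], y[j], x2[j], y2[j], rep(x2[i], length(j)), rep(y2[i], length(j)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    # collinear overlap: treat touching (product == 0 with overlap) as intersection
    col <- (d1 == 0 & d2 == 0)
    if (any(col)) {
      jj <- j[col]
      ov <- pmin(pmax(x[i], x2[i]), pmax(x[jj], x2[jj])) >=
            pmax(pmin(x[i], x2[i]), pmin(x[jj], x2[jj])) &
            pmin(pmax(y[i], y2[i]), pmax(y[jj], y2[jj])) >=
            pmax(pmin(y[i], y2[i]), pmin(y[jj], y2[jj]))
      if (any(ov)) return(FALSE)
    }
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Resample a closed polyline to equally spaced points
#'
#' Discretises a closed boundary into `n_points` positions equally spaced by
#' arc length along the closed polyline, starting at the original first
#' vertex. Targets that land (to within `1e-9` of the perimeter, relatively)
#' on an existing vertex are snapped onto it, so resampling an already-uniform
#' boundary of the same size is an exact identity.
#'
#' @param boundary A [closed_boundary()] (or data frame with `x`, `y`).
#' @param n_points Number of output points (at least 8).
#' @return A `closed_boundary` with `n_points` rows, CCW order preserved.
#' @export
resample_closed_polyline <- function(boundary, n_points) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 8) {
    stop("`n_points` must be a single integer >= 8", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  b <- as_boundary(boundary)
  x <- c(b$x, b$x[1]); y <- c(b$y, b$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  if (per <= 0) stop("degenerate boundary: zero perimeter", call. = FALSE)
  targets <- per * (seq_len(n_points) - 1) / n_points
  # snap targets onto existing vertices when essentially coincident
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  tol <- 1e-9 * per
  lo_snap <- abs(targets - cum[idx]) <= tol
  hi_snap <- abs(targets - cum[idx + 1]) <= tol
  t_frac <- (targets - cum[idx]) / seg[idx]
  t_frac[lo_snap] <- 0
  t_frac[hi_snap] <- 1
  out_x <- x[idx] + t_frac * (x[idx + 1] - x[idx])
  out_y <- y[idx] + t_frac * (y[idx + 1] - y[idx])
  closed_boundary(tibble::tibble(x = out_x, y = out_y), check = FALSE)
}

# accept either a closed_boundary or a bare data frame of points
as_boundary <- function(boundary, check = TRUE) {
  if (inherits(boundary, "closed_boundary")) return(boundary)
  closed_boundary(boundary, check = check)
}

#' Exterior unit normals of a closed boundary
#'
#' The normal at vertex i is the unit vector perpendicular to the chord from
#' vertex i-1 to vertex i+1 (cyclic indexing), oriented away from the polygon
#' interior. The chord stands in for the tangent of the underlying smooth
#' curve.
#'
#' @param boundary A [closed_boundary()] in CCW order.
#' @return An N x 2 matrix of unit normal vectors (columns `nx`, `ny`).
#' @export
exterior_normals <- function(boundary) {
  b <- as_boundary(boundary)
  x <- b$x; y <- b$y
  n <- length(x)
  ip <- c(n, seq_len(n - 1L))   # i - 1
  inx <- c(seq_len(n)[-1], 1L)  # i + 1
  cx <- x[inx] - x[ip]
  cy <- y[inx] - y[ip]
  len <- sqrt(cx^2 + cy^2)
  if (any(len == 0)) {
    stop("degenerate geometry: coincident neighbour points at element ",
         which(len == 0)[1], call. = FALSE)
  }
  # CCW traversal (positive shoelace area): outward normal is the clockwise
  # rotation of the tangent, (ty, -tx)
  normals <- cbind(nx = cy / len, ny = -cx / len)
  normals
}
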