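#' Read an image stack from TIFF
#'
#' Accepts a multi-page TIFF file or a directory of equally shaped single-page
#' TIFFs (lexicographic filename order = z order). Integer samples (8/16 bit)
#' are widened losslessly to double precision; all downstream computation is
#' in doubles so means and differences of intensities are never truncated.
#'
#' @param path A TIFF file or a directory of TIFFs.
#' @return A height x width x n_slices numeric array.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read `", path, "`: no such file", call. = FALSE)
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                    full.names = TRUE))
  } else path
  if (length(files) == 0) stop("no TIFF files in `", path, "`", call. = FALSE)
  pages <- list()
  for (f in files) {
    pg <- tryCatch(tiff::readTIFF(f, all = TRUE, as.is = TRUE),
                   error = function(e) {
                     stop("failed to read TIFF `", f, "`: ",
                          conditionMessage(e), call. = FALSE)
                   })
    pages <- c(pages, pg)
  }
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    stop("format error: slices have mixed shapes", call. = FALSE)
  }
  out <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of multi-channel
    out[, , z] <- as.numeric(p)
  }
  out
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities must be integers in [0, 65535] (the phantom generator emits
#' integer counts); they are stored losslessly at 16 bits so a write/read
#' round trip is bit-identical.
#'
#' @param stack A 3D array or list of matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  slices <- as_slice_list(stack)
  vals <- unlist(lapply(slices, range))
  if (min(vals) < 0 || max(vals) > 65535 ||
      any(vapply(slices, function(s) any(s != round(s)), logical(1)))) {
    stop("stack intensities must be integers in [0, 65535] for 16-bit TIFF",
         call. = FALSE)
  }
  tiff::writeTIFF(lapply(slices, function(s) s / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Average-pool (bin) an image stack
#'
#' Merges `kx` x `ky` x `kz` blocks of voxels into one by assigning the
#' arithmetic mean of the block — the standard resolution/speed trade used to
#' bring microscope data to isotropic voxels. Trailing partial blocks are
#' averaged over their actual extent.
#'
#' @param stack A 3D array or list of matrices.
#' @param kx,ky,kz Binning factors along x (columns), y (rows), z (slices).
#' @return A binned 3D array of size `ceiling(dim / k)`.
#' @export
bin_pixels <- function(stack, kx = 1, ky = 1, kz = 1) {
  stopifnot(kx >= 1, ky >= 1, kz >= 1)
  slices <- as_slice_list(stack)
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]]); nz <- length(slices)
  gy <- ceiling(h / ky); gx <- ceiling(w / kx); gz <- ceiling(nz / kz)
  row_g <- (seq_len(h) - 1) %/% ky + 1
  col_g <- (seq_len(w) - 1) %/% kx + 1
  bin2d <- function(m) {
    # group rows then columns by block index; rowsum keeps double precision
    t(rowsum(t(rowsum(m, row_g)), col_g)) /
      tcrossprod(tabulate(row_g, gy), tabulate(col_g, gx))
  }
  binned <- lapply(slices, bin2d)
  out <- array(0, dim = c(gy, gx, gz))
  z_g <- (seq_len(nz) - 1) %/% kz + 1
  for (zz in seq_len(gz)) {
    members <- which(z_g == zz)
    out[, , zz] <- Reduce(`+`, binned[members]) / length(members)
  }
  out
}

#' Read and write contour files
#'
#' Contours are stored as JSON: `{"points": [[x, y], ...], "closed": true,
#' "slice": z}`. Coordinates round-trip at full double precision.
#'
#' @param path File path.
#' @return `read_contour()`: a [closed_boundary()] with attribute `"slice"`.
#' @export
read_contour <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed contour JSON `", path, "`: ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(obj$closed) || !isTRUE(obj$closed)) {
    stop("contour file must have \"closed\": true", call. = FALSE)
  }
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  b <- closed_boundary(tibble::tibble(x = pts[, 1], y = pts[, 2]))
  attr(b, "slice") <- obj$slice
  b
}

#' @param boundary A [closed_boundary()].
#' @param slice Slice index recorded in the file.
#' @rdname read_contour
#' @export
write_contour <- function(boundary, path, slice = 1) {
  b <- as_boundary(boundary, check = FALSE)
  jsonlite::write_json(
    list(points = unname(cbind(b$x, b$y)), closed = TRUE, slice = slice),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Export a reconstructed surface
#'
#' `write_surface()` stores all contours plus voxel size as one JSON file.
#' `write_surface_obj()` writes a Wavefront OBJ triangle mesh: each contour
#' ring contributes its N vertices (z scaled by the voxel size) and every
#' pair of consecutive rings is joined by a band of 2N triangles using
#' matching vertex indices.
#'
#' @param model A `surface_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(model, path) {
  stopifnot(inherits(model, "surface_model"))
  jsonlite::write_json(list(
    voxel_size = model$voxel_size,
    z_range = model$z_range,
    boundaries = lapply(seq_along(model$boundaries), function(i) {
      b <- model$boundaries[[i]]
      list(slice = model$z_range[1] + i - 1L,
           points = unname(cbind(b$x, b$y)), closed = TRUE)
    })
  ), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a surface JSON written by [write_surface()]
#'
#' @param path File path.
#' @return A `surface_model`.
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bs <- lapply(seq_len(nrow(obj$boundaries)), function(i) {
    pts <- obj$boundaries$points[[i]]
    closed_boundary(tibble::tibble(x = pts[, 1], y = pts[, 2]), check = FALSE)
  })
  structure(list(boundaries = bs, voxel_size = as.numeric(obj$voxel_size),
                 z_range = as.integer(obj$z_range),
                 per_slice = tibble::tibble(z = obj$boundaries$slice,
                                            iterations = NA_integer_,
                                            residual = NA_real_,
                                            converged = NA, failed = NA)),
            class = "surface_model")
}

#' @rdname write_surface
#' @export
write_surface_obj <- function(model, path) {
  stopifnot(inherits(model, "surface_model"))
  nz <- length(model$boundaries)
  n <- nrow(model$boundaries[[1]])
  vs <- model$voxel_size
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangulated contour-band surface", con)
  for (i in seq_len(nz)) {
    b <- model$boundaries[[i]]
    z <- (model$z_range[1] + i - 1) * vs[3]
    writeLines(sprintf("v %.6f %.6f %.6f", b$x * vs[1], b$y * vs[2], z), con)
  }
  if (nz >= 2) {
    for (i in seq_len(nz - 1)) {
      a0 <- (i - 1) * n
      b0 <- i * n
      j <- seq_len(n)
      jn <- c(j[-1], 1L)
      writeLines(c(sprintf("f %d %d %d", a0 + j, a0 + jn, b0 + j),
                   sprintf("f %d %d %d", a0 + jn, b0 + jn, b0 + j)), con)
    }
  }
  invisible(path)
}
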