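#' Voxel grid: one channel of a 3D image stack with physical geometry
#'
#' A `voxel_grid` wraps a 3D numeric array together with its anisotropic
#' voxel spacing in micrometers, an origin offset, and a channel name.
#' Array axis order is (x, y, z); index `[i, j, k]` has physical center
#' `origin + ((i, j, k) - 1) * spacing` in micrometers.
#'
#' @param data numeric 3D array (a 2D matrix is promoted to a single slice).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in um, all > 0.
#' @param origin numeric length-3, physical position of voxel (1,1,1) in um.
#' @param channel channel name, e.g. "green", "red", "mx04", "fitc".
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0), channel = "") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("voxel_grid data must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (um)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("grid must be non-empty", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         channel = as.character(channel)),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid '%s' %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um>\n",
    x$channel, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical field extent of a grid in micrometers, per axis
#' @param grid a `voxel_grid`.
#' @return numeric length-3 extent in um.
#' @export
grid_extent <- function(grid) dim(grid$data) * grid$spacing

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("channel geometry mismatch (dims or spacing differ)", call. = FALSE)
  invisible(TRUE)
}

#' Read a (multi-page) TIFF into a voxel grid
#'
#' Pages are stacked along z. Values are returned as stored by [tiff::readTIFF]
#' (floating point in \[0, 1\] for integer TIFFs).
#'
#' @param path TIFF file path.
#' @inheritParams voxel_grid
#' @export
read_stack_tiff <- function(path, spacing, channel = "") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra samples
    t(p) # readTIFF returns row = y; store x fastest
  })
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  voxel_grid(arr, spacing, channel = channel)
}

#' Write a voxel grid as a multi-page TIFF
#'
#' Data are rescaled to \[0, 1\] by `scale` and written as 16-bit pages,
#' or written verbatim as 32-bit float when `float = TRUE`.
#'
#' @param grid a `voxel_grid`.
#' @param path output path.
#' @param scale divisor applied before writing 16-bit (ignored for float).
#' @param float write 32-bit float samples instead of 16-bit integer.
#' @export
write_stack_tiff <- function(grid, path, scale = max(grid$data, 1), float = FALSE) {
  pages <- lapply(seq_len(dim(grid$data)[3]), function(k) t(grid$data[, , k]))
  if (float) {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    pages <- lapply(pages, function(p) pmin(pmax(p / scale, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}
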