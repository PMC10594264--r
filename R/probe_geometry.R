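#' Rotate a 2D electrode footprint into a 3D binary mask
#'
#' Embeds the footprint as a plane and rotates it about the image-x
#' (medio-lateral) axis so the shank descends through the stack at the
#' insertion angle, as when referencing in-vivo stacks to the implantation
#' geometry. Resampling is nearest-neighbor, which preserves binarity.
#'
#' The pivot line is the footprint row at `pivot_y_um` placed at depth
#' `z0_um`; a footprint point at in-plane distance `u` from the pivot maps to
#' `(y, z) = (pivot + u*cos(theta), z0 + u*sin(theta))`.
#'
#' @param footprint logical/0-1 matrix (x by y), nonzero = electrode.
#' @param angle_deg rotation angle in degrees, in \[0, 90).
#' @param target_dim integer length-3 output dimensions (x, y, z).
#' @param spacing voxel spacing (dx, dy, dz) um of the target grid.
#' @param footprint_spacing pixel spacing (dx, dy) um of the footprint
#'   (defaults to the lateral target spacing).
#' @param thickness_um physical thickness of the embedded plate (defaults to
#'   the axial spacing, one slab at 0 degrees).
#' @param pivot_y_um y-coordinate (um) of the rotation axis. Default 0.
#' @param z0_um depth (um) at which the pivot line sits. Default 0.
#' @return binary `voxel_grid` with attribute `angle_deg`.
#' @export
rotate_footprint <- function(footprint, angle_deg, target_dim, spacing,
                             footprint_spacing = spacing[1:2],
                             thickness_um = spacing[3],
                             pivot_y_um = 0, z0_um = 0) {
  footprint <- footprint != 0
  if (!any(footprint)) stop("footprint mask is empty", call. = FALSE)
  if (angle_deg < 0 || angle_deg >= 90)
    stop("angle must be in [0, 90) degrees", call. = FALSE)
  target_dim <- as.integer(target_dim)
  theta <- angle_deg * pi / 180
  nfx <- nrow(footprint)
  nfy <- ncol(footprint)

  nx <- target_dim[1]; ny <- target_dim[2]; nz <- target_dim[3]
  out <- array(FALSE, dim = c(nx, ny, nz))
  nxe <- min(nx, nfx) # footprint x maps 1:1 onto grid x (same lateral scale)

  yc <- (seq_len(ny) - 1) * spacing[2] - pivot_y_um
  for (k in seq_len(nz)) {
    zc <- (k - 1) * spacing[3] - z0_um
    # inverse rotation: in-plane coordinate u, out-of-plane offset w
    u <- yc * cos(theta) + zc * sin(theta)
    w <- -yc * sin(theta) + zc * cos(theta)
    jnn <- ceiling(u / footprint_spacing[2] + 0.5) # nearest footprint row
    sel <- which(abs(w) <= thickness_um / 2 & jnn >= 1 & jnn <= nfy)
    for (j in sel) out[seq_len(nxe), j, k] <- footprint[seq_len(nxe), jnn[j]]
  }
  if (!any(out))
    stop("rotation placed the footprint entirely out of bounds", call. = FALSE)
  g <- voxel_grid(out * 1, spacing, channel = "probe_mask")
  attr(g, "angle_deg") <- angle_deg
  g
}

#' Anisotropic 3D Euclidean distance map of an electrode mask
#'
#' Each voxel of the result holds the minimal Euclidean distance in
#' micrometers (voxel-center to voxel-center, anisotropy-corrected) to any
#' mask voxel. Mask voxels hold exactly 0. The transform is an exact
#' separable parabolic-envelope EDT.
#'
#' @param mask binary `voxel_grid` (nonzero = electrode surface).
#' @return `distance_map` object (a `voxel_grid` subclass with provenance).
#' @export
compute_distance_map <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"))
  m <- mask$data != 0
  if (!any(m)) stop("electrode mask is empty", call. = FALSE)
  d <- edt3d_cpp(as.logical(m), dim(m), mask$spacing)
  dim(d) <- dim(m)
  g <- voxel_grid(d, mask$spacing, mask$origin, channel = "distance_um")
  g$provenance <- list(mask_channel = mask$channel,
                       angle_deg = attr(mask, "angle_deg"))
  class(g) <- c("distance_map", class(g))
  g
}

#' Annotate segmented objects with distance to the electrode surface
#'
#' Looks up the distance-map value at the voxel nearest to each object's
#' real-valued centroid (ties between voxel centers resolve toward the lower
#' index). Objects whose centroid falls outside the map are flagged with
#' `distance_missing = TRUE` rather than dropped; ordering is preserved.
#'
#' @param objects data.frame with centroid columns `x_um`, `y_um`, `z_um`.
#' @param dmap a `distance_map`.
#' @return `objects` with added `distance_um` and `distance_missing` columns.
#' @export
object_distances <- function(objects, dmap) {
  stopifnot(inherits(dmap, "distance_map"))
  if (nrow(objects) == 0) {
    objects$distance_um <- numeric(0)
    objects$distance_missing <- logical(0)
    return(objects)
  }
  dm <- dim(dmap$data)
  sp <- dmap$spacing
  idx <- function(coord, d, n) {
    i <- ceiling((coord - 0) / d + 0.5) # voxel centers at (i-1)*d; ties -> lower
    ifelse(i >= 1 & i <= n, i, NA_integer_)
  }
  i <- idx(objects$x_um, sp[1], dm[1])
  j <- idx(objects$y_um, sp[2], dm[2])
  k <- idx(objects$z_um, sp[3], dm[3])
  ok <- !is.na(i) & !is.na(j) & !is.na(k)
  d <- rep(NA_real_, nrow(objects))
  d[ok] <- dmap$data[cbind(i[ok], j[ok], k[ok])]
  objects$distance_um <- d
  objects$distance_missing <- !ok
  objects
}
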