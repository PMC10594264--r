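#' Segmentation filter-chain configuration
#'
#' Parameters of the background-suppression and object-labeling chain used
#' for lipofuscin granules, methoxy-X04 deposits and 2D plaque areas.
#'
#' @param gaussian_sigma sigma (px) of the Gaussian whose blurred image is
#'   subtracted from the original (large-scale background removal). Default 20.
#' @param bp_small,bp_large bandpass structure sizes (px): realized as a
#'   difference of Gaussians keeping features between the two scales.
#' @param median_radius radius (px) of the median filter (0 disables).
#' @param despeckle apply a final 3x3 median (ImageJ 'Despeckle' definition).
#' @param threshold_k SD multiplier k of the `mean + k * SD` intensity
#'   threshold. Default 2.5.
#' @param min_voxels minimum connected-component size kept (voxels/pixels).
#'   Default 10: after two 3x3 median passes the noise field is laterally
#'   correlated, so smaller suprathreshold patches arise from noise alone;
#'   10 voxels matches the smallest plausible granule at default sampling.
#' @param connectivity 3D connectivity for labeling: 6, 18 or 26.
#' @return a `filter_config` list.
#' @export
filter_config <- function(gaussian_sigma = 20, bp_small = 1, bp_large = 20,
                          median_radius = 1, despeckle = TRUE,
                          threshold_k = 2.5, min_voxels = 10,
                          connectivity = 26) {
  stopifnot(gaussian_sigma > 0, bp_small < bp_large, threshold_k > 0,
            connectivity %in% c(6, 18, 26))
  structure(list(gaussian_sigma = gaussian_sigma, bp_small = bp_small,
                 bp_large = bp_large, median_radius = median_radius,
                 despeckle = despeckle, threshold_k = threshold_k,
                 min_voxels = min_voxels, connectivity = connectivity),
            class = "filter_config")
}

gblur2d <- function(m, sigma) gauss2d_cpp(m, sigma)

#' Suppress image background via the Gaussian-subtraction filter chain
#'
#' Applies, per z-slice and in order: subtraction of a heavily Gaussian-blurred
#' copy (removes slowly varying background), a bandpass (difference of
#' Gaussians), a median filter, and an optional 3x3-median despeckle.
#' Negative values are clipped to zero.
#'
#' @param grid a `voxel_grid` (a 2D matrix is accepted and returned as such).
#' @param cfg a [filter_config].
#' @return filtered object of the same shape/class as the input.
#' @export
suppress_background <- function(grid, cfg = filter_config()) {
  is_grid <- inherits(grid, "voxel_grid")
  arr <- if (is_grid) grid$data else grid
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  stopifnot(all(is.finite(arr)))
  for (k in seq_len(dim(arr)[3])) {
    s <- arr[, , k]
    s <- s - gblur2d(s, cfg$gaussian_sigma)          # background subtraction
    # bandpass as difference of Gaussians; structure size s_px ~ 2 * sigma
    s <- gblur2d(s, cfg$bp_small / 2) - gblur2d(s, cfg$bp_large / 2)
    if (cfg$median_radius > 0) s <- median2d_cpp(s, as.integer(cfg$median_radius))
    if (cfg$despeckle) s <- median2d_cpp(s, 1L)
    arr[, , k] <- pmax(s, 0)
  }
  if (!is_grid) {
    out <- arr[, , 1]
    return(out)
  }
  out <- grid
  out$data <- arr
  out
}

#' Binarize by a mean + k*SD intensity threshold
#'
#' The threshold is `mean + k * SD` computed over all voxels of the input
#' (optionally excluding voxels of a probe mask); voxels strictly above the
#' threshold are foreground. A zero-variance image yields an empty mask.
#'
#' @param grid `voxel_grid` or numeric array/matrix.
#' @param k SD multiplier (> 0).
#' @param exclude logical array of voxels excluded from the mean/SD statistics
#'   (e.g. the electrode mask), or NULL.
#' @return logical array (same dims) with attribute `threshold` (the cut used).
#' @export
threshold_binary <- function(grid, k = 2.5, exclude = NULL) {
  stopifnot(k > 0)
  arr <- if (inherits(grid, "voxel_grid")) grid$data else grid
  vals <- if (is.null(exclude)) arr else arr[!exclude]
  thr <- mean(vals) + k * stats::sd(as.numeric(vals))
  if (!is.finite(thr)) thr <- Inf
  out <- arr > thr
  attr(out, "threshold") <- thr
  out
}

#' Label connected components and compute object statistics
#'
#' Connected components of a binary volume under the configured connectivity;
#' components smaller than `cfg$min_voxels` are discarded. Centroids are
#' unweighted voxel-center means in micrometers; volume is voxel count times
#' voxel volume.
#'
#' @param binary logical 3D array (or 2D matrix) of foreground voxels.
#' @param spacing voxel spacing (dx, dy, dz) um; give `c(dx, dy, 1)` for 2D.
#' @param cfg a [filter_config] (connectivity, min size).
#' @param intensity optional array of the same shape whose per-object mean is
#'   reported as `mean_intensity`.
#' @return data.frame: id, x_um, y_um, z_um, voxels, volume_um3, mean_intensity.
#' @export
label_objects <- function(binary, spacing, cfg = filter_config(),
                          intensity = NULL) {
  if (is.matrix(binary)) dim(binary) <- c(dim(binary), 1L)
  dm <- dim(binary)
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), voxels = integer(0),
                      volume_um3 = numeric(0), mean_intensity = numeric(0))
  idx <- which(binary)
  if (length(idx) == 0) return(empty)
  lab <- label3d_cpp(as.logical(binary), dm, as.integer(cfg$connectivity))
  labs <- lab[idx]
  cnt <- tabulate(labs)
  keep <- which(cnt >= cfg$min_voxels)
  if (length(keep) == 0) return(empty)
  sel <- labs %in% keep
  idx <- idx[sel]
  labs <- labs[sel]
  # voxel indices -> physical coordinates
  i <- (idx - 1) %% dm[1]
  j <- ((idx - 1) %/% dm[1]) %% dm[2]
  kk <- (idx - 1) %/% (dm[1] * dm[2])
  f <- factor(labs, levels = keep)
  n <- as.integer(table(f))
  voxvol <- prod(spacing)
  inten <- if (is.null(intensity)) rep(NA_real_, length(keep)) else
    as.numeric(tapply(intensity[idx], f, mean))
  data.frame(
    id = seq_along(keep),
    x_um = as.numeric(tapply(i, f, mean)) * spacing[1],
    y_um = as.numeric(tapply(j, f, mean)) * spacing[2],
    z_um = as.numeric(tapply(kk, f, mean)) * spacing[3],
    voxels = n,
    volume_um3 = n * voxvol,
    mean_intensity = inten
  )
}

#' Linear spectral unmixing of a multi-channel stack
#'
#' Per-voxel solve of `observed = M %*% source` for a square invertible mixing
#' matrix `M`. Negative solutions are clipped to zero and the clipped fraction
#' recorded as attribute `clip_fraction`. The identity matrix returns the
#' input unchanged.
#'
#' @param stack list of `voxel_grid` channels sharing geometry.
#' @param mixing square mixing matrix (rows = observed, cols = source).
#' @return list of unmixed `voxel_grid`s (channel names preserved).
#' @export
unmix_channels <- function(stack, mixing) {
  nc <- length(stack)
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != nc || ncol(mixing) != nc)
    stop("mixing matrix must be square with size = channel count", call. = FALSE)
  if (abs(det(mixing)) < 1e-12) stop("mixing matrix is singular", call. = FALSE)
  for (ch in stack[-1]) stopifnot_same_geometry(stack[[1]], ch)
  inv <- solve(mixing)
  obs <- vapply(stack, function(g) as.numeric(g$data),
                numeric(length(stack[[1]]$data)))
  src <- obs %*% t(inv)
  clip <- mean(src < -1e-12)
  src[src < 0] <- 0
  out <- stack
  for (c in seq_len(nc)) {
    out[[c]]$data <- array(src[, c], dim = dim(stack[[c]]$data))
  }
  attr(out, "clip_fraction") <- clip
  out
}

#' Detect lipofuscin granules by dual-channel 1:1 colocalization
#'
#' Lipofuscin autofluorescence appears with equal intensity in the green and
#' red emission channels. Each channel is background-suppressed and
#' thresholded at `mean + k * SD`; candidate voxels must be suprathreshold in
#' BOTH channels and have a red/green ratio within
#' `[1/(1+tol), 1+tol]` after normalizing each filtered channel to its mean.
#' Candidates are then labeled into objects.
#'
#' @param green,red `voxel_grid`s sharing geometry.
#' @param cfg a [filter_config].
#' @param ratio_tol ratio tolerance around 1:1 (default 0.25).
#' @param exclude optional logical array excluded from threshold statistics.
#' @return object data.frame as from [label_objects].
#' @export
detect_lipofuscin <- function(green, red, cfg = filter_config(),
                              ratio_tol = 0.25, exclude = NULL) {
  stopifnot_same_geometry(green, red)
  gf <- suppress_background(green, cfg)
  rf <- suppress_background(red, cfg)
  gb <- threshold_binary(gf, cfg$threshold_k, exclude)
  rb <- threshold_binary(rf, cfg$threshold_k, exclude)
  gm <- mean(gf$data)
  rm_ <- mean(rf$data)
  gn <- gf$data / ifelse(gm > 0, gm, 1)
  rn <- rf$data / ifelse(rm_ > 0, rm_, 1)
  ratio <- rn / pmax(gn, 1e-12)
  cand <- gb & rb & ratio >= 1 / (1 + ratio_tol) & ratio <= 1 + ratio_tol
  label_objects(cand, green$spacing, cfg, intensity = (gf$data + rf$data) / 2)
}

#' 2D plaque area segmentation for stained sections
#'
#' Runs the same filter chain, threshold and labeling on a single 2D image
#' (e.g. 6E10-stained amyloid plaques) and reports per-object areas.
#'
#' @param image numeric matrix.
#' @param pixel_size pixel edge length in um.
#' @param cfg a [filter_config]; 2D labeling uses 8-connectivity.
#' @return data.frame: id, x_um, y_um, pixels, area_um2, mean_intensity.
#' @export
plaque_area_2d <- function(image, pixel_size, cfg = filter_config()) {
  stopifnot(is.matrix(image))
  f <- suppress_background(image, cfg)
  b <- threshold_binary(f, cfg$threshold_k)
  obj <- label_objects(b, c(pixel_size, pixel_size, 1), cfg, intensity = f)
  data.frame(id = obj$id, x_um = obj$x_um, y_um = obj$y_um,
             pixels = obj$voxels,
             area_um2 = obj$voxels * pixel_size^2,
             mean_intensity = obj$mean_intensity)
}
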