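#' Scene specification for the synthetic two-photon generator
#'
#' Describes one imaging field: physical size, anisotropic voxel spacing,
#' probe geometry, the radial granule density model, the plaque cohort and
#' its per-hemisphere growth, session days, the noise model and inter-session
#' drift. Identical spec + seed yields bit-identical output everywhere
#' downstream.
#'
#' Default geometry mirrors the acquisition this generator emulates: lateral
#' pixel size 635.9/1024 um, axial step 2.5 um, insertion angle 30 degrees,
#' shank reaching ~300 um depth; sessions every 14 days over 12 weeks (seven
#' timepoints).
#'
#' @param field_um physical field extent (x, y, z) in um.
#' @param spacing voxel spacing (dx, dy, dz) in um.
#' @param probe list: `width_um`, `thickness_um`, `length_um`, `angle_deg`.
#' @param granules list: `baseline_per_mm3`, `amplitude_per_mm3` (surface
#'   excess density), `decay_um` (exponential decay length), `radius_median_um`,
#'   `radius_sigma_log` (log-normal), optional `n_total` to condition the
#'   point process on an exact count.
#' @param plaques list: `n` (named ipsi/contra counts), `radius_range_um`,
#'   `growth` (named per-session multiplicative volume growth, > -1),
#'   `min_separation_um`.
#' @param sessions strictly increasing vector of imaging days.
#' @param noise list: `background` (offset, a.u.), `poisson` (logical),
#'   `poisson_scale` (photons per intensity unit), `read_sd` (Gaussian).
#' @param snr peak object amplitude over background noise SD (granules).
#' @param snr_plaque same for plaques and vessels.
#' @param psf_sigma_um lateral PSF stand-in (Gaussian sigma, um); 0 disables.
#' @param drift_um max absolute random-walk drift step per session per axis.
#' @param vessels list: `n_tubes`, `radius_um`.
#' @param seed integer RNG seed.
#' @return validated `scene_spec` object.
#' @export
scene_spec <- function(field_um = c(317.95, 317.95, 300),
                       spacing = c(635.9 / 1024, 635.9 / 1024, 2.5),
                       probe = list(width_um = 60, thickness_um = 15,
                                    length_um = 600, angle_deg = 30),
                       granules = list(baseline_per_mm3 = 2000,
                                       amplitude_per_mm3 = 50000,
                                       decay_um = 50,
                                       radius_median_um = 2.5,
                                       radius_sigma_log = 0.25,
                                       n_total = 200),
                       plaques = list(n = c(ipsi = 25, contra = 27),
                                      radius_range_um = c(5, 10),
                                      growth = c(ipsi = 0, contra = 0.08),
                                      min_separation_um = 30),
                       sessions = seq(0, 84, by = 14),
                       noise = list(background = 50, poisson = TRUE,
                                    poisson_scale = 1, read_sd = 2),
                       snr = 5, snr_plaque = 10,
                       psf_sigma_um = 0.5,
                       drift_um = c(10, 10, 2.5),
                       vessels = list(n_tubes = 8, radius_um = 3),
                       seed = 1L) {
  stopifnot(all(field_um > 0), all(spacing > 0),
            probe$width_um > 0, probe$thickness_um > 0, probe$length_um > 0,
            probe$angle_deg >= 0, probe$angle_deg < 90,
            granules$decay_um > 0, granules$baseline_per_mm3 >= 0,
            granules$amplitude_per_mm3 >= 0,
            granules$radius_median_um > 0, granules$radius_sigma_log >= 0,
            all(plaques$growth > -1), all(plaques$n >= 0),
            all(diff(sessions) > 0),
            noise$background >= 0, noise$read_sd >= 0,
            snr > 0, snr_plaque > 0, psf_sigma_um >= 0)
  structure(list(field_um = field_um, spacing = spacing, probe = probe,
                 granules = granules, plaques = plaques, sessions = sessions,
                 noise = noise, snr = snr, snr_plaque = snr_plaque,
                 psf_sigma_um = psf_sigma_um, drift_um = drift_um,
                 vessels = vessels, seed = as.integer(seed)),
            class = "scene_spec")
}

scene_dims <- function(spec) pmax(1L, as.integer(round(spec$field_um / spec$spacing)))

# SD of the background noise under the configured noise model
background_noise_sd <- function(spec) {
  v <- spec$noise$read_sd^2
  if (isTRUE(spec$noise$poisson))
    v <- v + spec$noise$background / spec$noise$poisson_scale
  sqrt(max(v, 1e-12))
}

#' Generate the 3D probe mask (and its 2D footprint) for a scene
#'
#' Builds a rectangular shank footprint (width along x, length along y),
#' embeds it at the field surface and rotates it about the x axis by the
#' insertion angle via [rotate_footprint]. Errors when the rotated shank
#' would descend beyond the axial field extent.
#'
#' @param spec a [scene_spec].
#' @return list: `mask` (binary `voxel_grid`), `footprint` (logical matrix).
#' @export
generate_probe_mask <- function(spec) {
  dims <- scene_dims(spec)
  theta <- spec$probe$angle_deg * pi / 180
  depth <- spec$probe$length_um * sin(theta)
  if (depth > spec$field_um[3] + spec$spacing[3] / 2)
    stop(sprintf(
      "probe descends to %.0f um but the field is only %.0f um deep",
      depth, spec$field_um[3]), call. = FALSE)
  nfx <- max(1L, round(spec$probe$width_um / spec$spacing[1]))
  nfy <- max(1L, round(spec$probe$length_um / spec$spacing[2]))
  fp <- matrix(TRUE, nrow = nfx, ncol = nfy)
  # centre the shank in x
  x0 <- max(0L, as.integer(round((dims[1] - nfx) / 2)))
  full_fp <- matrix(FALSE, nrow = dims[1], ncol = nfy)
  full_fp[x0 + seq_len(min(nfx, dims[1] - x0)), ] <- TRUE
  mask <- rotate_footprint(full_fp, spec$probe$angle_deg, dims, spec$spacing,
                           thickness_um = max(spec$probe$thickness_um,
                                              spec$spacing[3]))
  list(mask = mask, footprint = fp)
}

#' Sample ground-truth lipofuscin granules from a radial density model
#'
#' Inhomogeneous point process with intensity
#' `baseline + amplitude * exp(-d / decay)` (densities per mm^3, d = distance
#' to the electrode surface in um). Centers are drawn per voxel weight and
#' jittered uniformly within the voxel; no center falls inside the probe mask
#' or within a safety margin of the field border (so every truth object lies
#' fully in the field). Radii are log-normal.
#'
#' When `n_total` is set the process is conditioned on that exact count;
#' otherwise the realized count is Poisson with the integrated intensity
#' (recorded as attribute `expected_count`).
#'
#' @param spec a [scene_spec].
#' @param dmap `distance_map` of the probe (or NULL for a probe-free
#'   hemisphere, in which case density is the baseline everywhere).
#' @param probe_mask optional binary `voxel_grid` of excluded voxels.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame: x_um, y_um, z_um, radius_um, volume_um3, distance_um.
#' @export
sample_granules <- function(spec, dmap = NULL, probe_mask = NULL,
                            seed = spec$seed) {
  dims <- scene_dims(spec)
  g <- spec$granules
  voxvol <- prod(spec$spacing)
  if (is.null(dmap)) {
    dens <- rep(g$baseline_per_mm3, prod(dims))
  } else {
    dens <- g$baseline_per_mm3 +
      g$amplitude_per_mm3 * exp(-as.numeric(dmap$data) / g$decay_um)
  }
  w <- dens * voxvol / 1e9 # per mm^3 -> expected count per voxel
  if (!is.null(probe_mask)) w[probe_mask$data != 0] <- 0
  # border margin: keep whole spheres inside the field
  margin <- stats::qlnorm(0.999, log(g$radius_median_um), g$radius_sigma_log) +
    spec$drift_um
  coord_ok <- function(n, d, m) {
    c_um <- (seq_len(n) - 1) * d
    c_um >= m & c_um <= (n - 1) * d - m
  }
  okx <- coord_ok(dims[1], spec$spacing[1], margin[1])
  oky <- coord_ok(dims[2], spec$spacing[2], margin[2])
  okz <- coord_ok(dims[3], spec$spacing[3], margin[3])
  dim(w) <- dims
  w[!okx, , ] <- 0; w[, !oky, ] <- 0; w[, , !okz] <- 0
  w <- as.numeric(w)
  expected <- sum(w)
  set.seed(seed)
  n <- if (!is.null(g$n_total)) g$n_total else stats::rpois(1, expected)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  i <- (idx - 1) %% dims[1]
  j <- ((idx - 1) %/% dims[1]) %% dims[2]
  k <- (idx - 1) %/% (dims[1] * dims[2])
  jit <- matrix(stats::runif(3 * n, -0.5, 0.5), ncol = 3)
  x <- (i + jit[, 1]) * spec$spacing[1]
  y <- (j + jit[, 2]) * spec$spacing[2]
  z <- (k + jit[, 3]) * spec$spacing[3]
  r <- stats::rlnorm(n, log(g$radius_median_um), g$radius_sigma_log)
  d <- if (is.null(dmap)) rep(NA_real_, n) else as.numeric(dmap$data)[idx]
  out <- data.frame(x_um = x, y_um = y, z_um = z, radius_um = r,
                    volume_um3 = 4 / 3 * pi * r^3, distance_um = d)
  attr(out, "expected_count") <- expected
  out
}

#' Sample ground-truth amyloid plaques for one hemisphere
#'
#' Uniform positions with a minimum pairwise separation and a border margin;
#' initial radii uniform in the configured range. Per-session true volumes
#' follow `v_s = v_1 * (1 + growth)^(s - 1)` (multiplicative volume growth
#' per session), i.e. radii grow with the cube root.
#'
#' @param spec a [scene_spec].
#' @param hemisphere "ipsi" or "contra" (selects count and growth rate).
#' @param seed RNG seed.
#' @return data.frame: plaque id, center, initial radius, growth, hemisphere,
#'   with attribute `volume_series` (plaques x sessions matrix of true um^3).
#' @export
sample_plaques <- function(spec, hemisphere = c("ipsi", "contra"),
                           seed = spec$seed + 101L) {
  hemisphere <- match.arg(hemisphere)
  p <- spec$plaques
  n <- unname(p$n[hemisphere])
  growth <- unname(p$growth[hemisphere])
  ns <- length(spec$sessions)
  set.seed(seed)
  rmax <- p$radius_range_um[2] * (1 + max(growth, 0))^((ns - 1) / 3)
  margin <- rmax + spec$drift_um + 2 # stay in frame under capped drift
  lo <- margin
  hi <- spec$field_um - margin
  centers <- matrix(NA_real_, nrow = n, ncol = 3)
  placed <- 0
  tries <- 0
  while (placed < n && tries < 20000) {
    tries <- tries + 1
    cand <- stats::runif(3, lo, hi)
    if (placed > 0) {
      dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
      if (min(dd) < p$min_separation_um) next
    }
    placed <- placed + 1
    centers[placed, ] <- cand
  }
  if (placed < n)
    stop("could not place plaques with the requested separation", call. = FALSE)
  r0 <- stats::runif(n, p$radius_range_um[1], p$radius_range_um[2])
  v0 <- 4 / 3 * pi * r0^3
  vol <- outer(v0, (1 + growth)^(seq_len(ns) - 1))
  out <- data.frame(plaque = seq_len(n), x_um = centers[, 1],
                    y_um = centers[, 2], z_um = centers[, 3],
                    radius0_um = r0, growth = growth,
                    hemisphere = hemisphere)
  attr(out, "volume_series") <- vol
  out
}

# seeded set of bright tubes reused across sessions (vasculature landmark)
sample_vessels <- function(spec, seed) {
  set.seed(seed)
  nt <- spec$vessels$n_tubes
  lapply(seq_len(nt), function(i) {
    start <- stats::runif(3, c(0, 0, 10), c(spec$field_um[1], spec$field_um[2],
                                            spec$field_um[3] - 10))
    ang <- stats::runif(1, 0, 2 * pi)
    dirv <- c(cos(ang), sin(ang), stats::runif(1, -0.15, 0.15))
    dirv <- dirv / sqrt(sum(dirv^2))
    list(start = start, dir = dirv)
  })
}

# Per-session drift offsets: zero at session 1, then a reflected random walk
# with per-session steps up to drift_um/2 and total excursion capped at
# drift_um per axis (sessions are re-found on vasculature, so drift does not
# accumulate without bound).
sample_drift <- function(spec, seed) {
  ns <- length(spec$sessions)
  set.seed(seed)
  off <- matrix(0, nrow = ns, ncol = 3)
  for (ax in 1:3) {
    cap <- spec$drift_um[ax]
    x <- 0
    for (s in 2:ns) {
      x <- x + stats::runif(1, -cap / 2, cap / 2)
      if (x > cap) x <- 2 * cap - x
      if (x < -cap) x <- -2 * cap - x
      off[s, ax] <- x
    }
  }
  off
}

#' Build a complete synthetic scene for one hemisphere
#'
#' Assembles probe mask and distance map (ipsilateral only), ground-truth
#' granules, plaques, the fixed vessel tree and per-session drift offsets.
#'
#' @param spec a [scene_spec].
#' @param hemisphere "ipsi" (with probe) or "contra" (intact).
#' @param granules,plaques logical switches for which truth to generate.
#' @return a `scene` list with elements spec, hemisphere, probe (mask or
#'   NULL), dmap, granules, plaques, vessels, drift.
#' @export
build_scene <- function(spec, hemisphere = c("ipsi", "contra"),
                        granules = TRUE, plaques = TRUE) {
  hemisphere <- match.arg(hemisphere)
  hseed <- spec$seed + ifelse(hemisphere == "ipsi", 0L, 5000L)
  probe <- NULL
  dmap <- NULL
  if (hemisphere == "ipsi") {
    probe <- generate_probe_mask(spec)
    dmap <- compute_distance_map(probe$mask)
  }
  gr <- if (granules)
    sample_granules(spec, dmap, probe$mask, seed = hseed + 11L) else NULL
  pl <- if (plaques && unname(spec$plaques$n[hemisphere]) > 0)
    sample_plaques(spec, hemisphere, seed = hseed + 101L) else NULL
  structure(list(spec = spec, hemisphere = hemisphere, probe = probe,
                 dmap = dmap, granules = gr, plaques = pl,
                 vessels = sample_vessels(spec, hseed + 211L),
                 drift = sample_drift(spec, hseed + 307L)),
            class = "scene")
}

# stamp solid spheres (voxel-center indicator) into an array, additively;
# the array is modified in place (callers own a fresh allocation)
stamp_spheres <- function(arr, centers, radii, amplitude, spacing) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  stamp_spheres_cpp(arr, dim(arr), centers, as.numeric(radii),
                    amplitude, spacing)
  arr
}

#' Render one imaging session of a synthetic scene
#'
#' Rasterizes truth objects into the requested channels (lipofuscin granules
#' with identical amplitude into green AND red; plaques into the mx04
#' channel; the fixed vessel tree into fitc), applies the session drift
#' translation to all object positions, blurs laterally by the PSF stand-in,
#' and adds Poisson + Gaussian read noise on top of the background offset.
#'
#' @param scene a scene from [build_scene].
#' @param session session index (1-based into `spec$sessions`).
#' @param channels subset of c("green", "red", "mx04", "fitc").
#' @return named list of `voxel_grid`s.
#' @export
render_session <- function(scene, session,
                           channels = c("green", "red", "mx04", "fitc")) {
  spec <- scene$spec
  stopifnot(session >= 1, session <= length(spec$sessions))
  dims <- scene_dims(spec)
  off <- scene$drift[session, ]
  bg_sd <- background_noise_sd(spec)
  amp_g <- spec$snr * bg_sd
  amp_p <- spec$snr_plaque * bg_sd
  hsh <- ifelse(scene$hemisphere == "ipsi", 0L, 50000L)
  out <- list()
  for (ch in channels) {
    arr <- array(0, dim = dims)
    if (ch %in% c("green", "red") && !is.null(scene$granules)) {
      gdf <- scene$granules
      ctr <- sweep(cbind(gdf$x_um, gdf$y_um, gdf$z_um), 2, -off)
      arr <- stamp_spheres(arr, ctr, gdf$radius_um, amp_g, spec$spacing)
    }
    if (ch == "mx04" && !is.null(scene$plaques)) {
      pdf_ <- scene$plaques
      vols <- attr(pdf_, "volume_series")
      rq <- (vols[, session] / (4 / 3 * pi))^(1 / 3)
      ctr <- sweep(cbind(pdf_$x_um, pdf_$y_um, pdf_$z_um), 2, -off)
      arr <- stamp_spheres(arr, ctr, rq, amp_p, spec$spacing)
    }
    if (ch == "fitc") {
      step <- min(spec$spacing[1:2])
      tmax <- 2 * max(spec$field_um)
      ts <- seq(-tmax, tmax, by = 4 * step)
      pts <- list()
      for (tube in scene$vessels) {
        p <- cbind(tube$start[1] + ts * tube$dir[1] + off[1],
                   tube$start[2] + ts * tube$dir[2] + off[2],
                   tube$start[3] + ts * tube$dir[3] + off[3])
        rv <- spec$vessels$radius_um
        keep <- p[, 1] > -rv & p[, 2] > -rv & p[, 3] > -rv &
          p[, 1] < spec$field_um[1] + rv & p[, 2] < spec$field_um[2] + rv &
          p[, 3] < spec$field_um[3] + rv
        pts[[length(pts) + 1]] <- p[keep, , drop = FALSE]
      }
      pts <- do.call(rbind, pts)
      if (nrow(pts) > 0)
        arr <- stamp_spheres(arr, pts, rep(spec$vessels$radius_um, nrow(pts)),
                             amp_p, spec$spacing)
      arr <- pmin(arr, amp_p) # overlapping stamps saturate, tube-like
    }
    if (spec$psf_sigma_um > 0) {
      sig_px <- spec$psf_sigma_um / spec$spacing[1]
      for (k in seq_len(dims[3])) arr[, , k] <- gblur2d(arr[, , k], sig_px)
    }
    arr <- arr + spec$noise$background
    chix <- match(ch, c("green", "red", "mx04", "fitc"))
    set.seed(spec$seed + 7919L * session + hsh + 13L * chix)
    n <- length(arr)
    if (isTRUE(spec$noise$poisson)) {
      sc <- spec$noise$poisson_scale
      arr <- array(stats::rpois(n, pmax(arr, 0) * sc) / sc, dim = dims)
    }
    if (spec$noise$read_sd > 0)
      arr <- arr + array(stats::rnorm(n, 0, spec$noise$read_sd), dim = dims)
    out[[ch]] <- voxel_grid(arr, spec$spacing, channel = ch)
  }
  out
}

#' Generate a synthetic immunostained section pair (ipsi + contralateral)
#'
#' The marker channel follows a radial mean-intensity profile around the
#' probe center; the nuclei channel contains disk-shaped nuclei at a radial
#' density. The contralateral image uses the distance-independent baseline
#' parameters of both models (flat marker, uniform nuclei).
#'
#' Marker profile types: `flat` (f(r) = 1), `step` (f = amp for r < r0,
#' else 1) and `exp` (f = 1 + (amp - 1) exp(-r / decay)); the rendered mean
#' is `baseline * f(r)`.
#'
#' @param marker list: `baseline`, `type`, `amp`, `r0_um`, `decay_um`.
#' @param nuclei list: `density_per_mm2` (baseline), `dip_frac` (density
#'   multiplier inside `r0_um`), `r0_um`, `radius_um` (nucleus disk radius),
#'   `amplitude`.
#' @param img_px image size in pixels (square).
#' @param pixel_um pixel size in um.
#' @param tissue_radius_um radius of the stained tissue disc; beyond it the
#'   image holds only the slide floor + noise (the unstained margin used to
#'   estimate the background-noise threshold).
#' @param floor slide background offset outside the tissue (a.u.).
#' @param noise_sd Gaussian pixel noise SD.
#' @param seed RNG seed.
#' @return list: `ipsi`/`contra` (each list(marker, nuclei) matrices),
#'   `center_um`, `pixel_um`, `truth` (parameter echo + nucleus centers).
#' @export
generate_ihc_section <- function(marker = list(baseline = 100, type = "exp",
                                               amp = 3, r0_um = 50,
                                               decay_um = 75),
                                 nuclei = list(density_per_mm2 = 1000,
                                               dip_frac = 1, r0_um = 50,
                                               radius_um = 3.5,
                                               amplitude = 150),
                                 img_px = 1024,
                                 pixel_um = 635.9 / 1024,
                                 tissue_radius_um = 310, floor = 5,
                                 noise_sd = 5, seed = 1L) {
  center <- (img_px / 2) * pixel_um
  xs <- (seq_len(img_px) - 1) * pixel_um - center
  r <- sqrt(outer(xs^2, xs^2, "+"))
  fr <- switch(marker$type,
    flat = matrix(1, img_px, img_px),
    step = ifelse(r < marker$r0_um, marker$amp, 1),
    exp  = 1 + (marker$amp - 1) * exp(-r / marker$decay_um),
    stop("unknown marker profile type"))
  tissue <- r <= tissue_radius_um
  render_side <- function(profile, dens_field, seed_off) {
    set.seed(seed + seed_off)
    m <- floor + marker$baseline * profile * tissue +
      matrix(stats::rnorm(img_px^2, 0, noise_sd), img_px, img_px)
    # nuclei: thinned point field over the pixel grid
    area_mm2 <- pixel_um^2 / 1e6
    lam <- dens_field * area_mm2
    n <- stats::rpois(1, sum(lam))
    idx <- sample.int(length(lam), n, replace = TRUE, prob = lam)
    cx <- ((idx - 1) %% img_px + stats::runif(n, -0.5, 0.5)) * pixel_um
    cy <- ((idx - 1) %/% img_px + stats::runif(n, -0.5, 0.5)) * pixel_um
    nuc <- matrix(0, img_px, img_px)
    rpx <- ceiling(nuclei$radius_um / pixel_um)
    for (q in seq_len(n)) {
      i0 <- max(1, round(cx[q] / pixel_um) + 1 - rpx)
      i1 <- min(img_px, round(cx[q] / pixel_um) + 1 + rpx)
      j0 <- max(1, round(cy[q] / pixel_um) + 1 - rpx)
      j1 <- min(img_px, round(cy[q] / pixel_um) + 1 + rpx)
      if (i0 > i1 || j0 > j1) next
      px <- (seq(i0, i1) - 1) * pixel_um - cx[q]
      py <- (seq(j0, j1) - 1) * pixel_um - cy[q]
      d2 <- outer(px^2, py^2, "+")
      nuc[i0:i1, j0:j1] <- pmax(nuc[i0:i1, j0:j1],
                                nuclei$amplitude * (d2 <= nuclei$radius_um^2))
    }
    nuc <- nuc + matrix(stats::rnorm(img_px^2, 0, noise_sd), img_px, img_px)
    list(marker = m, nuclei = nuc,
         nucleus_centers = data.frame(x_um = cx, y_um = cy))
  }
  dens_ipsi <- matrix(nuclei$density_per_mm2, img_px, img_px)
  dens_ipsi[r < nuclei$r0_um] <- nuclei$density_per_mm2 * nuclei$dip_frac
  dens_ipsi[!tissue] <- 0
  dens_contra <- matrix(nuclei$density_per_mm2, img_px, img_px)
  dens_contra[!tissue] <- 0
  ipsi <- render_side(fr, dens_ipsi, 0L)
  contra <- render_side(matrix(1, img_px, img_px), dens_contra, 1000L)
  list(ipsi = ipsi[c("marker", "nuclei")],
       contra = contra[c("marker", "nuclei")],
       center_um = c(center, center), pixel_um = pixel_um,
       truth = list(marker = marker, nuclei = nuclei,
                    ipsi_nuclei = ipsi$nucleus_centers,
                    contra_nuclei = contra$nucleus_centers))
}
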