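test_that("scene spec validates its invariants", {
  expect_s3_class(scene_spec(), "scene_spec")
  expect_error(scene_spec(field_um = c(-1, 100, 100)))
  expect_error(scene_spec(sessions = c(0, 14, 14)))
  expect_error(scene_spec(plaques = list(n = c(ipsi = 1, contra = 1),
                                         radius_range_um = c(4, 6),
                                         growth = c(ipsi = -1.5, contra = 0),
                                         min_separation_um = 10)))
})

small_spec <- function(...) scene_spec(
  field_um = c(99.4, 99.4, 60), spacing = c(99.4 / 160, 99.4 / 160, 2.5),
  probe = list(width_um = 20, thickness_um = 10, length_um = 100, angle_deg = 30),
  granules = list(baseline_per_mm3 = 20000, amplitude_per_mm3 = 3e5,
                  decay_um = 25, radius_median_um = 2.2,
                  radius_sigma_log = 0.2, n_total = 40),
  plaques = list(n = c(ipsi = 3, contra = 3), radius_range_um = c(4, 6),
                 growth = c(ipsi = 0, contra = 0.1), min_separation_um = 18),
  drift_um = c(4, 4, 1.5), vessels = list(n_tubes = 3, radius_um = 2.5),
  seed = 33L, ...)

test_that("probe mask volume approximates the analytic slab and errors when too deep", {
  spec <- scene_spec(field_um = c(198.8, 496, 200),
                     spacing = c(0.62, 0.62, 2.5),
                     probe = list(width_um = 60, thickness_um = 15,
                                  length_um = 380, angle_deg = 30))
  pm <- generate_probe_mask(spec)
  vol <- sum(pm$mask$data != 0) * prod(spec$spacing)
  expect_equal(vol, 60 * 380 * 15, tolerance = 0.1)
  # axial extent ~ L sin(theta)
  occ <- which(apply(pm$mask$data != 0, 3, any))
  expect_equal((max(occ) - min(occ)) * 2.5, 380 * sin(pi / 6), tolerance = 0.05)
  too_deep <- scene_spec(field_um = c(99.4, 99.4, 60),
                         spacing = c(0.62, 0.62, 2.5),
                         probe = list(width_um = 20, thickness_um = 10,
                                      length_um = 400, angle_deg = 30))
  expect_error(generate_probe_mask(too_deep), "deep")
})

test_that("granule sampling follows the exponential distance model", {
  spec <- small_spec()
  pm <- generate_probe_mask(spec)
  dmap <- compute_distance_map(pm$mask)
  gr <- sample_granules(spec, dmap, pm$mask, seed = 1)
  expect_equal(nrow(gr), 40)
  expect_equal(gr$volume_um3, 4 / 3 * pi * gr$radius_um^3)
  # no center inside the probe mask
  idx <- cbind(ceiling(gr$x_um / spec$spacing[1] + 0.5),
               ceiling(gr$y_um / spec$spacing[2] + 0.5),
               ceiling(gr$z_um / spec$spacing[3] + 0.5))
  expect_true(all(pm$mask$data[idx] == 0))
  # monotone decay: volume-corrected bin densities decrease with distance
  vox_d <- dmap$data[pm$mask$data == 0]
  bins <- seq(0, 60, by = 15)
  binvol <- as.numeric(table(cut(vox_d, bins))) * prod(spec$spacing)
  cnt <- as.numeric(table(cut(gr$distance_um, bins)))
  dens <- cnt / binvol
  expect_true(all(diff(dens) < 0))
})

test_that("amplitude zero gives a spatially homogeneous process", {
  spec <- small_spec()
  spec$granules$amplitude_per_mm3 <- 0
  spec$granules$n_total <- 400
  pm <- generate_probe_mask(spec)
  dmap <- compute_distance_map(pm$mask)
  gr <- sample_granules(spec, dmap, pm$mask, seed = 2)
  # eligible voxels: outside the probe and the placement margin
  dims <- dim(dmap$data)
  marg <- qlnorm(0.999, log(spec$granules$radius_median_um),
                 spec$granules$radius_sigma_log) + spec$drift_um
  ok <- function(n, d, m) {
    c_um <- (seq_len(n) - 1) * d
    c_um >= m & c_um <= (n - 1) * d - m
  }
  elig <- array(TRUE, dims)
  elig[!ok(dims[1], spec$spacing[1], marg[1]), , ] <- FALSE
  elig[, !ok(dims[2], spec$spacing[2], marg[2]), ] <- FALSE
  elig[, , !ok(dims[3], spec$spacing[3], marg[3])] <- FALSE
  elig[pm$mask$data != 0] <- FALSE
  vox_d <- dmap$data[elig]
  bins <- c(0, 10, 20, 30, 45, 70)
  vol <- as.numeric(table(cut(vox_d, bins)))
  cnt <- as.numeric(table(cut(gr$distance_um, bins)))
  # counts proportional to bin volume (chi-square GOF)
  keep <- vol > 0
  p <- suppressWarnings(
    chisq.test(cnt[keep], p = vol[keep] / sum(vol[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("unconditioned realized counts match the integrated intensity", {
  spec <- small_spec()
  spec$granules$n_total <- NULL
  pm <- generate_probe_mask(spec)
  dmap <- compute_distance_map(pm$mask)
  counts <- vapply(1:40, function(s)
    nrow(sample_granules(spec, dmap, pm$mask, seed = s)), numeric(1))
  gr <- sample_granules(spec, dmap, pm$mask, seed = 1)
  expected <- attr(gr, "expected_count")
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 40))
})

test_that("rendering is deterministic and noiseless rasterization is exact", {
  spec <- small_spec()
  scene <- build_scene(spec, "ipsi")
  a <- render_session(scene, 1, channels = c("green", "red"))
  b <- render_session(scene, 1, channels = c("green", "red"))
  expect_identical(a$green$data, b$green$data)
  expect_identical(a$red$data, b$red$data)
  # 1:1 channels are equal pre-noise: disable noise and blur
  spec2 <- small_spec()
  spec2$noise <- list(background = 0, poisson = FALSE, poisson_scale = 1, read_sd = 0)
  spec2$psf_sigma_um <- 0
  sc2 <- build_scene(spec2, "ipsi", plaques = FALSE)
  ch <- render_session(sc2, 1, channels = c("green", "red"))
  expect_identical(ch$green$data, ch$red$data)
  # voxelized volume within a one-voxel-thick shell of the analytic volume
  vol_total <- sum(ch$green$data > 0) * prod(spec2$spacing)
  shell <- max(spec2$spacing) * sum(4 * pi * sc2$granules$radius_um^2)
  expect_lt(abs(vol_total - sum(sc2$granules$volume_um3)), shell)
})

test_that("plaque growth raises suprathreshold MX04 voxel counts across sessions", {
  spec <- small_spec()
  scene <- build_scene(spec, "contra", granules = FALSE)
  bgsd <- sqrt(50 + 4)
  thr <- 50 + 5 * bgsd # truth threshold well above noise
  n1 <- sum(render_session(scene, 1, "mx04")$mx04$data > thr)
  n3 <- sum(render_session(scene, 3, "mx04")$mx04$data > thr)
  expect_gt(n3, n1)
  # hemisphere separation: ipsi growth never affects contra renders
  spec_hi <- small_spec()
  spec_hi$plaques$growth["ipsi"] <- 0.5
  sc_a <- build_scene(spec_hi, "contra", granules = FALSE)
  ch_a <- render_session(sc_a, 3, "mx04")
  expect_identical(ch_a$mx04$data, render_session(scene, 3, "mx04")$mx04$data)
})

test_that("IHC sections self-normalize flat and scale nuclei counts with area", {
  sec <- generate_ihc_section(marker = list(baseline = 100, type = "flat"),
                              noise_sd = 0, seed = 3)
  thr <- background_threshold(sec$contra$marker, sec$center_um, sec$pixel_um)
  pr <- normalize_to_contralateral(
    bin_intensity(sec$ipsi$marker, sec$center_um, sec$pixel_um, threshold = thr),
    sec$contra$marker, threshold = thr)
  expect_true(all(abs(pr$normalized - 1) < 1e-12))
  sec2 <- generate_ihc_section(
    marker = list(baseline = 100, type = "flat"),
    nuclei = list(density_per_mm2 = 1000, dip_frac = 1, r0_um = 50,
                  radius_um = 3.5, amplitude = 150),
    noise_sd = 3, seed = 4)
  truthn <- sec2$truth$ipsi_nuclei
  rr <- sqrt((truthn$x_um - sec2$center_um[1])^2 + (truthn$y_um - sec2$center_um[2])^2)
  cnt <- table(cut(rr, seq(0, 300, 50)))
  area <- pi * diff(seq(0, 300, 50)^2) / 1e6 # mm^2
  lam <- 1000 * area
  expect_true(all(abs(cnt - lam) < 4 * sqrt(lam) + 2))
})
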