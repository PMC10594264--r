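test_that("spectral unmixing inverts a known bleed-through and keeps identities", {
  set.seed(3)
  sp <- c(1, 1, 2)
  src1 <- array(runif(4 * 4 * 3, 0, 100), c(4, 4, 3))
  src2 <- array(runif(4 * 4 * 3, 0, 100), c(4, 4, 3))
  M <- matrix(c(1, 0.2, 0.2, 1), 2, 2) # 20% bleed each way
  obs1 <- M[1, 1] * src1 + M[1, 2] * src2
  obs2 <- M[2, 1] * src1 + M[2, 2] * src2
  stack <- list(voxel_grid(obs1, sp, channel = "g"),
                voxel_grid(obs2, sp, channel = "r"))
  un <- unmix_channels(stack, M)
  rms <- sqrt(mean((un[[1]]$data - src1)^2)) / mean(src1)
  expect_lt(rms, 0.01)
  # identity mixing returns input unchanged
  id <- unmix_channels(stack, diag(2))
  expect_equal(id[[1]]$data, obs1)
  # an all-zero channel stays zero
  z <- list(voxel_grid(array(0, c(2, 2, 2)), sp),
            voxel_grid(array(1, c(2, 2, 2)), sp))
  expect_true(all(unmix_channels(z, diag(2))[[1]]$data == 0))
  expect_error(unmix_channels(stack, matrix(1, 2, 2)), "singular")
})

test_that("background suppression removes DC, gradients and hot pixels but keeps blobs", {
  cfg <- filter_config()
  expect_true(all(suppress_background(matrix(7, 64, 64), cfg) == 0))
  grad <- outer(seq(0, 50, length.out = 128), rep(1, 128))
  img <- grad
  img[60:62, 60:62] <- img[60:62, 60:62] + 40
  f <- suppress_background(img, cfg)
  outside <- matrix(TRUE, 128, 128); outside[55:68, 55:68] <- FALSE
  expect_gte(max(f[55:68, 55:68]), 0.5 * 40)   # blob contrast retained
  expect_lt(max(f[outside]), 0.05 * 50)        # gradient removed
  hot <- matrix(0, 64, 64); hot[30, 30] <- 100
  expect_lt(suppress_background(hot, cfg)[30, 30], 2)
})

test_that("mean + k*SD threshold is strict and empty on constant images", {
  set.seed(4)
  arr <- array(rnorm(4000, 100, 10), c(20, 20, 10))
  b <- threshold_binary(arr, 2.5)
  thr <- mean(arr) + 2.5 * sd(arr)
  expect_equal(attr(b, "threshold"), thr)
  expect_identical(as.logical(b), as.logical(arr > thr)) # strict >
  expect_false(any(threshold_binary(array(5, c(3, 3, 3)), 2.5)))
  # Gaussian noise: suprathreshold fraction ~ upper 2.5-sigma tail (0.62%)
  set.seed(5)
  g <- array(rnorm(5e5), c(100, 100, 50))
  expect_equal(mean(threshold_binary(g, 2.5)), pnorm(2.5, lower.tail = FALSE),
               tolerance = 0.35)
})

test_that("labeling separates, merges by connectivity, and matches flood fill", {
  cfg1 <- filter_config(min_voxels = 1)
  b <- array(FALSE, c(8, 8, 3))
  b[1:2, 1:2, 1:2] <- TRUE
  b[6:7, 6:7, 1:2] <- TRUE
  o <- label_objects(b, c(1, 1, 1), cfg1)
  expect_equal(nrow(o), 2)
  expect_equal(o$voxels, c(8L, 8L))
  expect_equal(o$volume_um3, c(8, 8))
  # touching at one corner: merged under 26, separate under 6
  b2 <- array(FALSE, c(4, 4, 2)); b2[1:2, 1:2, 1] <- TRUE; b2[3:4, 3:4, 2] <- TRUE
  expect_equal(nrow(label_objects(b2, c(1, 1, 1), filter_config(min_voxels = 1, connectivity = 26))), 1)
  expect_equal(nrow(label_objects(b2, c(1, 1, 1), filter_config(min_voxels = 1, connectivity = 6))), 2)
  # random sparse masks against the exhaustive oracle
  set.seed(12)
  for (rep in 1:6) {
    m <- array(runif(10 * 9 * 8) < 0.12, c(10, 9, 8))
    for (conn in c(6, 26)) {
      o <- label_objects(m, c(1, 1, 1), filter_config(min_voxels = 1, connectivity = conn))
      bf <- brute_force_label(m, conn)
      expect_equal(nrow(o), max(bf))
      expect_equal(sort(o$voxels), sort(as.integer(table(bf[bf > 0]))))
    }
  }
  expect_equal(nrow(label_objects(array(FALSE, c(3, 3, 3)), c(1, 1, 1), cfg1)), 0)
})

test_that("lipofuscin detection requires coincident 1:1 signal in both channels", {
  spec <- scene_spec(
    field_um = c(99.4, 99.4, 50), spacing = c(99.4 / 160, 99.4 / 160, 2.5),
    probe = list(width_um = 20, thickness_um = 10, length_um = 90, angle_deg = 30),
    granules = list(baseline_per_mm3 = 0, amplitude_per_mm3 = 0, decay_um = 50,
                    radius_median_um = 2.5, radius_sigma_log = 0.15, n_total = 0),
    snr = 8, seed = 21L)
  dims <- c(160, 160, 20)
  bgsd <- sqrt(50 + 4)
  set.seed(22)
  mk <- function(objs, amp) {
    arr <- array(0, dims)
    for (q in seq_len(nrow(objs)))
      arr <- arr + amp * (sqrt(outer(outer(
        ((seq_len(dims[1]) - 1) * spec$spacing[1] - objs$x[q])^2,
        ((seq_len(dims[2]) - 1) * spec$spacing[2] - objs$y[q])^2, "+"),
        ((seq_len(dims[3]) - 1) * spec$spacing[3] - objs$z[q])^2, "+")) <= objs$r[q])
    arr
  }
  lip <- data.frame(x = c(25, 60, 40), y = c(25, 70, 55), z = c(15, 25, 35), r = 2.5)
  red_only <- data.frame(x = 80, y = 30, z = 20, r = 4)
  g <- mk(lip, 8 * bgsd) + 50
  r <- mk(lip, 8 * bgsd) + mk(red_only, 8 * bgsd) + 50
  set.seed(23)
  g <- g + array(rnorm(length(g), 0, bgsd), dims)
  set.seed(24)
  r <- r + array(rnorm(length(r), 0, bgsd), dims)
  gg <- voxel_grid(g, spec$spacing, channel = "green")
  rr <- voxel_grid(r, spec$spacing, channel = "red")
  obj <- detect_lipofuscin(gg, rr, filter_config(), ratio_tol = 0.25)
  # all three 1:1 objects found, the red-only distractor rejected
  expect_equal(nrow(obj), 3)
  for (q in seq_len(3)) {
    d <- sqrt((obj$x_um - lip$x[q])^2 + (obj$y_um - lip$y[q])^2 + (obj$z_um - lip$z[q])^2)
    expect_lt(min(d), 3)
  }
  d_distr <- sqrt((obj$x_um - 80)^2 + (obj$y_um - 30)^2 + (obj$z_um - 20)^2)
  expect_gt(min(d_distr), 5)
  # a zero ratio tolerance admits (almost) nothing under noise
  obj0 <- detect_lipofuscin(gg, rr, filter_config(), ratio_tol = 0)
  expect_lte(nrow(obj0), 0)
  expect_error(detect_lipofuscin(gg, voxel_grid(r[1:10, 1:10, 1:2], spec$spacing)),
               "geometry")
})

test_that("2D plaque areas recover disk geometry", {
  px <- 0.62
  n <- 400
  xs <- (seq_len(n) - 1) * px
  img <- matrix(10, n, n)
  disk <- function(img, cx, cy, rad, amp) {
    r2 <- outer((xs - cx)^2, (xs - cy)^2, "+")
    img + amp * (r2 <= rad^2)
  }
  img <- disk(img, 60, 60, 10, 100)
  img <- disk(img, 180, 180, 20, 100) # 4x the area
  set.seed(31)
  img <- img + matrix(rnorm(n * n, 0, 3), n, n)
  obj <- plaque_area_2d(img, px, filter_config(bp_large = 64))
  obj <- obj[order(obj$area_um2), ]
  expect_equal(nrow(obj), 2)
  expect_equal(obj$area_um2[1], 100 * pi, tolerance = 0.1)
  expect_equal(obj$area_um2[2] / obj$area_um2[1], 4, tolerance = 0.1)
  empty <- matrix(5, 64, 64)
  expect_equal(nrow(plaque_area_2d(empty, px)), 0)
})
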