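sp_iso <- c(1, 1, 1)

test_that("zero-degree rotation embeds the footprint as a single slab", {
  fp <- matrix(TRUE, 10, 20)
  m <- rotate_footprint(fp, 0, c(16, 30, 8), c(0.62, 0.62, 2.5))
  occ <- which(apply(m$data != 0, 3, any))
  expect_equal(occ, 1L)
  expect_true(all(m$data[1:10, 1:20, 1] == 1))
})

test_that("rotated plate spans the axial extent given by trigonometry", {
  sp <- c(0.62, 0.62, 2.5)
  L <- 150 # um in-plane length
  fp <- matrix(TRUE, 8, round(L / sp[2]))
  m <- rotate_footprint(fp, 30, c(16, 250, 40), sp)
  occ <- which(apply(m$data != 0, 3, any))
  expect_lte(abs((max(occ) - min(occ) + 1) - round(L * sin(pi / 6) / sp[3])), 1)
})

test_that("empty footprint and out-of-bounds rotation raise errors", {
  expect_error(rotate_footprint(matrix(FALSE, 4, 4), 30, c(8, 8, 4), sp_iso),
               "empty")
  fp <- matrix(TRUE, 4, 4)
  expect_error(rotate_footprint(fp, 89, c(8, 8, 4), c(1, 1, 1), z0_um = -500),
               "out of bounds")
  expect_error(rotate_footprint(fp, 95, c(8, 8, 4), sp_iso), "angle")
})

test_that("double 15-degree rotation nearly reproduces a single 30-degree one", {
  sp <- c(1, 1, 1)
  fp <- matrix(TRUE, 10, 20) # 200-voxel plate
  single <- rotate_footprint(fp, 30, c(12, 24, 16), sp,
                             thickness_um = 4)$data != 0
  # compose: nearest-neighbor resample of the 15-degree plate rotated 15 more
  first <- rotate_footprint(fp, 15, c(12, 24, 16), sp, thickness_um = 4)
  th <- 15 * pi / 180
  dm <- dim(first$data)
  twice <- array(FALSE, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) {
    y <- (j - 1) * sp[2]; z <- (k - 1) * sp[3]
    ys <- y * cos(th) + z * sin(th)
    zs <- -y * sin(th) + z * cos(th)
    jj <- ceiling(ys / sp[2] + 0.5); kk <- ceiling(zs / sp[3] + 0.5)
    if (jj >= 1 && jj <= dm[2] && kk >= 1 && kk <= dm[3])
      twice[, j, k] <- first$data[, jj, kk] != 0
  }
  jac <- sum(single & twice) / sum(single | twice)
  expect_false(identical(single, twice)) # NN resampling does not compose
  expect_gte(jac, 0.9)                   # but stays geometrically close
})

test_that("distance map solves Pythagorean and axis-scaled cases exactly", {
  m <- array(FALSE, c(9, 9, 3)); m[5, 5, 2] <- TRUE
  d <- compute_distance_map(voxel_grid(m * 1, sp_iso))
  expect_equal(d$data[8, 9, 2], 5)       # offset (3, 4, 0)
  expect_equal(d$data[5, 5, 2], 0)
  m2 <- array(FALSE, c(3, 3, 3)); m2[1, 1, 1] <- TRUE
  d2 <- compute_distance_map(voxel_grid(m2 * 1, c(1, 1, 2.5)))
  expect_equal(d2$data[1, 1, 3], 5)      # index offset (0, 0, 2) x 2.5 um
  expect_error(compute_distance_map(voxel_grid(array(0, c(3, 3, 3)), sp_iso)),
               "empty")
})

test_that("distance map matches the brute-force oracle on random masks", {
  set.seed(101)
  sp <- c(0.7, 1.1, 2.5)
  for (rep in 1:12) {
    dm <- c(sample(4:15, 1), sample(4:15, 1), sample(3:9, 1))
    m <- array(runif(prod(dm)) < 0.07, dim = dm)
    if (!any(m)) m[1, 2, 1] <- TRUE
    d <- compute_distance_map(voxel_grid(m * 1, sp))
    expect_equal(d$data, brute_force_edt(m, sp), tolerance = 1e-12)
  }
})

test_that("growing the mask never increases any distance", {
  set.seed(7)
  dm <- c(12, 10, 6)
  m <- array(runif(prod(dm)) < 0.05, dim = dm); m[3, 3, 3] <- TRUE
  d1 <- compute_distance_map(voxel_grid(m * 1, c(1, 1.4, 2)))
  m2 <- m; m2[10, 9, 5] <- TRUE; m2[1, 1, 1] <- TRUE
  d2 <- compute_distance_map(voxel_grid(m2 * 1, c(1, 1.4, 2)))
  expect_true(all(d2$data <= d1$data + 1e-12))
})

test_that("object distances use the nearest voxel with ties toward lower index", {
  m <- array(FALSE, c(8, 8, 4)); m[2, 2, 2] <- TRUE
  d <- compute_distance_map(voxel_grid(m * 1, c(1, 1, 1)))
  obj <- data.frame(x_um = c(1, 1.5, 20), y_um = c(1, 1, 1), z_um = c(1, 1, 1))
  out <- object_distances(obj, d)
  expect_equal(out$distance_um[1], 0)            # centroid on the mask voxel
  expect_equal(out$distance_um[2], 0)            # halfway tie -> lower index
  expect_true(out$distance_missing[3])           # out of bounds, flagged
  expect_equal(nrow(out), 3)                     # ordering/rows preserved
})

test_that("centroid distance lookups agree with brute force within a voxel diagonal", {
  set.seed(11)
  sp <- c(0.8, 0.8, 2)
  dm <- c(14, 14, 8)
  m <- array(runif(prod(dm)) < 0.05, dim = dm); m[7, 7, 4] <- TRUE
  dmap <- compute_distance_map(voxel_grid(m * 1, sp))
  pts <- which(m, arr.ind = TRUE); pts <- sweep(pts - 1, 2, sp, "*")
  n <- 60
  obj <- data.frame(x_um = runif(n, 0, (dm[1] - 1) * sp[1]),
                    y_um = runif(n, 0, (dm[2] - 1) * sp[2]),
                    z_um = runif(n, 0, (dm[3] - 1) * sp[3]))
  out <- object_distances(obj, dmap)
  bf <- vapply(seq_len(n), function(q)
    sqrt(min(colSums((t(pts) - c(obj$x_um[q], obj$y_um[q], obj$z_um[q]))^2))),
    numeric(1))
  expect_true(all(abs(out$distance_um - bf) <= sqrt(sum(sp^2)) + 1e-9))
})

test_that("zero-degree rotation then distance map equals the planar embedding", {
  fp <- matrix(TRUE, 6, 9)
  sp <- c(1, 1, 2)
  m <- rotate_footprint(fp, 0, c(10, 12, 5), sp)
  d <- compute_distance_map(m)
  ref <- array(FALSE, c(10, 12, 5)); ref[1:6, 1:9, 1] <- TRUE
  dref <- compute_distance_map(voxel_grid(ref * 1, sp))
  expect_equal(d$data, dref$data)
})
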