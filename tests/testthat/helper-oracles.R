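# Brute-force oracles kept independent of the package's C++ kernels.

# O(n^2) nearest-mask-voxel Euclidean distance (anisotropic, um)
brute_force_edt <- function(mask, spacing) {
  dm <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  pts <- sweep(pts - 1, 2, spacing, "*")
  vox <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                               k = seq_len(dm[3])))
  q <- sweep(vox - 1, 2, spacing, "*")
  d2 <- Reduce(pmin, lapply(seq_len(nrow(pts)), function(r)
    (q[, 1] - pts[r, 1])^2 + (q[, 2] - pts[r, 2])^2 + (q[, 3] - pts[r, 3])^2))
  array(sqrt(d2), dim = dm)
}

# exhaustive queue-based flood fill for connected components
brute_force_label <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ai <- arrayInd(v, dm)
      for (r in seq_len(nrow(offs))) {
        nb <- ai + offs[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        li <- nb[1] + (nb[2] - 1) * dm[1] + (nb[3] - 1) * dm[1] * dm[2]
        if (mask[li] && lab[li] == 0) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# exhaustive minimal-total-distance one-to-one assignment (small n)
brute_force_assignment <- function(a, b, max_disp) {
  # a, b: matrices of centroids (rows); returns data.frame(i, j)
  na <- nrow(a); nb <- nrow(b)
  dmat <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j)
    sqrt(sum((a[i, ] - b[j, ])^2))))
  best <- NULL
  best_cost <- Inf
  k <- min(na, nb)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  subsets <- utils::combn(seq_len(nb), k, simplify = FALSE)
  for (ss in subsets) for (p in perms(ss)) {
    cost <- 0; ok <- TRUE
    pairs <- list()
    for (i in seq_len(k)) {
      d <- dmat[i, p[i]]
      if (d > max_disp) next
      cost <- cost + d
      pairs[[length(pairs) + 1]] <- c(i, p[i])
    }
    if (length(pairs) && cost / length(pairs) < best_cost) {
      best_cost <- cost / length(pairs)
      best <- do.call(rbind, pairs)
    }
  }
  best
}

# quick tiny scene for pipeline tests: 80 x 80 x 24 voxels
tiny_tracking_spec <- function(seed = 5L, growth = c(ipsi = 0, contra = 0.08),
                               sessions = seq(0, 28, by = 14)) {
  scene_spec(
    field_um = c(99.4, 99.4, 60),
    spacing = c(99.4 / 160, 99.4 / 160, 2.5),
    probe = list(width_um = 20, thickness_um = 10, length_um = 100,
                 angle_deg = 30),
    plaques = list(n = c(ipsi = 4, contra = 4), radius_range_um = c(4, 6),
                   growth = growth, min_separation_um = 18),
    sessions = sessions,
    drift_um = c(4, 4, 1.5),
    vessels = list(n_tubes = 4, radius_um = 2.5),
    seed = seed)
}
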