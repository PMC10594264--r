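#' Register imaging sessions on the vasculature channel
#'
#' Estimates a per-session rigid translation against a reference session by
#' maximizing the normalized cross-correlation (NCC) of the mean-subtracted
#' vessel channels, computed via FFT (circular). The integer peak is refined
#' to sub-voxel precision by separable quadratic interpolation. The reported
#' offset is the physical translation (um) of the session relative to the
#' reference: `session(x) ~ reference(x - offset)`.
#'
#' @param vessel_stacks list of `voxel_grid`s (one per session, shared
#'   geometry).
#' @param reference index of the reference session (default 1).
#' @param score_floor registrations scoring below this NCC are flagged
#'   `low_confidence` (default 0.3).
#' @return data.frame: session, dx_um, dy_um, dz_um, score, low_confidence.
#' @export
register_sessions <- function(vessel_stacks, reference = 1,
                              score_floor = 0.3) {
  ns <- length(vessel_stacks)
  stopifnot(ns >= 2)
  for (g in vessel_stacks[-1]) stopifnot_same_geometry(vessel_stacks[[1]], g)
  ref <- vessel_stacks[[reference]]$data
  if (stats::sd(ref) == 0) stop("reference vessel channel is constant", call. = FALSE)
  sp <- vessel_stacks[[reference]]$spacing
  dm <- dim(ref)
  a <- ref - mean(ref)
  fa <- stats::fft(a)
  na <- sqrt(sum(a^2))
  res <- data.frame(session = seq_len(ns), dx_um = 0, dy_um = 0, dz_um = 0,
                    score = 1, low_confidence = FALSE)
  qint <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) return(0)
    max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
  }
  for (s in setdiff(seq_len(ns), reference)) {
    b <- vessel_stacks[[s]]$data
    if (stats::sd(b) == 0)
      stop(sprintf("vessel channel of session %d is constant", s), call. = FALSE)
    b <- b - mean(b)
    cc <- Re(stats::fft(fa * Conj(stats::fft(b)), inverse = TRUE)) /
      (length(a) * na * sqrt(sum(b^2)))
    pk <- which.max(cc)
    pi_ <- arrayInd(pk, dm)
    # sub-voxel refinement per axis (wrapped neighbors)
    wrap <- function(i, n) ((i - 1) %% n) + 1
    sub <- numeric(3)
    for (ax in 1:3) {
      im <- pi_; ip <- pi_
      im[ax] <- wrap(pi_[ax] - 1, dm[ax])
      ip[ax] <- wrap(pi_[ax] + 1, dm[ax])
      sub[ax] <- qint(cc[im], cc[pk], cc[ip])
    }
    sh <- pi_ - 1 + sub
    sh <- ifelse(sh > dm / 2, sh - dm, sh) # wrap to signed shift
    # cc peaks at minus the displacement of session relative to reference
    res[s, c("dx_um", "dy_um", "dz_um")] <- -sh * sp
    res$score[s] <- max(cc)
    res$low_confidence[s] <- max(cc) < score_floor
  }
  res
}

#' Track objects across sessions by greedy nearest-centroid matching
#'
#' Centroids are first drift-corrected using the session registrations; then
#' objects are linked session-to-session, closest pair first, each object
#' used at most once, pairs farther than `max_disp_um` left unmatched.
#' Unmatched objects start new tracks. A track missing from at most
#' `gap_max` consecutive sessions may be re-linked (gap bridging); longer
#' absences terminate it.
#'
#' @param objects_by_session list (one per session) of object data.frames
#'   with columns id, x_um, y_um, z_um, volume_um3.
#' @param registrations data.frame from [register_sessions] (or NULL for no
#'   drift correction).
#' @param max_disp_um maximum allowed corrected displacement (default 20).
#' @param gap_max maximum bridged gap in sessions (default 1).
#' @return long data.frame: track, session, id, x_um, y_um, z_um,
#'   volume_um3 (one row per observation).
#' @export
match_objects <- function(objects_by_session, registrations = NULL,
                          max_disp_um = 20, gap_max = 1) {
  ns <- length(objects_by_session)
  corrected <- lapply(seq_len(ns), function(s) {
    df <- objects_by_session[[s]]
    if (!is.null(registrations) && nrow(df) > 0) {
      df$x_um <- df$x_um - registrations$dx_um[s]
      df$y_um <- df$y_um - registrations$dy_um[s]
      df$z_um <- df$z_um - registrations$dz_um[s]
    }
    df
  })
  tracks <- list() # each: list(last_xyz, last_session, rows)
  obs <- list()
  ntrack <- 0
  for (s in seq_len(ns)) {
    df <- corrected[[s]]
    nobj <- nrow(df)
    active <- which(vapply(tracks, function(tr)
      s - tr$last_session <= gap_max + 1, logical(1)))
    assigned_obj <- rep(FALSE, nobj)
    assigned_trk <- rep(FALSE, length(active))
    if (length(active) > 0 && nobj > 0) {
      tc <- t(vapply(tracks[active], function(tr) tr$last_xyz, numeric(3)))
      dmat <- outer(seq_len(nrow(tc)), seq_len(nobj),
                    Vectorize(function(a, b)
                      sqrt(sum((tc[a, ] - c(df$x_um[b], df$y_um[b], df$z_um[b]))^2))))
      ord <- order(dmat)
      for (o in ord) {
        if (dmat[o] > max_disp_um) break
        ai <- (o - 1) %% nrow(dmat) + 1
        bi <- (o - 1) %/% nrow(dmat) + 1
        if (assigned_trk[ai] || assigned_obj[bi]) next
        assigned_trk[ai] <- TRUE
        assigned_obj[bi] <- TRUE
        ti <- active[ai]
        tracks[[ti]]$last_xyz <- c(df$x_um[bi], df$y_um[bi], df$z_um[bi])
        tracks[[ti]]$last_session <- s
        obs[[length(obs) + 1]] <- data.frame(
          track = ti, session = s, id = df$id[bi], x_um = df$x_um[bi],
          y_um = df$y_um[bi], z_um = df$z_um[bi],
          volume_um3 = df$volume_um3[bi])
      }
    }
    for (bi in which(!assigned_obj)) {
      ntrack <- ntrack + 1
      tracks[[ntrack]] <- list(
        last_xyz = c(df$x_um[bi], df$y_um[bi], df$z_um[bi]), last_session = s)
      obs[[length(obs) + 1]] <- data.frame(
        track = ntrack, session = s, id = df$id[bi], x_um = df$x_um[bi],
        y_um = df$y_um[bi], z_um = df$z_um[bi], volume_um3 = df$volume_um3[bi])
    }
  }
  if (length(obs) == 0)
    return(data.frame(track = integer(0), session = integer(0),
                      id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), volume_um3 = numeric(0)))
  out <- do.call(rbind, obs)
  out[order(out$track, out$session), ]
}

#' Volume-change series of tracked plaques
#'
#' Adds per-observation `dvolume_um3` (v(t) - v(first session observed)) and
#' `pct_change` (100 * (v(t) - v(day 0)) / v(day 0)). Tracks not observed at
#' the first session are flagged `no_day0` and excluded from the percent
#' series (their `pct_change` is NA) while keeping the delta series.
#'
#' @param tracks long data.frame from [match_objects].
#' @param day0_session session index counted as day 0 (default 1).
#' @return `tracks` with added dvolume_um3, pct_change, no_day0 columns.
#' @export
volume_change <- function(tracks, day0_session = 1) {
  if (nrow(tracks) == 0) {
    tracks$dvolume_um3 <- numeric(0)
    tracks$pct_change <- numeric(0)
    tracks$no_day0 <- logical(0)
    return(tracks)
  }
  out <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$session), ]
    v0row <- tr$volume_um3[tr$session == day0_session]
    tr$dvolume_um3 <- tr$volume_um3 - tr$volume_um3[1]
    if (length(v0row) == 1 && v0row > 0) {
      tr$pct_change <- 100 * (tr$volume_um3 - v0row) / v0row
      tr$no_day0 <- FALSE
    } else {
      tr$pct_change <- NA_real_
      tr$no_day0 <- TRUE
    }
    tr
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
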