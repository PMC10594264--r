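#' Build (and validate) a run manifest
#'
#' A manifest describes one end-to-end run: mode, the scene specification
#' (synthetic mode) or file paths (user data), configuration and output
#' directory. In IHC mode every ipsilateral image must declare a
#' contralateral partner.
#'
#' @param mode "longitudinal" (two-photon z-stacks) or "ihc" (sections).
#' @param spec a [scene_spec] (synthetic runs).
#' @param sections list of section descriptors for IHC mode; each a list with
#'   `marker`/`nuclei` parameters or `ipsi`/`contra` image paths, plus
#'   `animal`, `group`, `timepoint`.
#' @param cfg a [filter_config] for granule-scale objects.
#' @param cfg_plaque a [filter_config] for plaque-scale objects; the default
#'   widens the bandpass to 64 px so the passband brackets the plaque
#'   diameter (~25 px) instead of shaving it.
#' @param out_dir output directory or NULL (no files written).
#' @param seed integer seed for the run.
#' @return validated `run_manifest`.
#' @export
run_manifest <- function(mode = c("longitudinal", "ihc"), spec = NULL,
                         sections = NULL, cfg = filter_config(),
                         cfg_plaque = filter_config(bp_large = 64),
                         out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "longitudinal") {
    if (is.null(spec)) stop("longitudinal mode requires a scene_spec", call. = FALSE)
    if (length(spec$sessions) < 2)
      stop("longitudinal mode requires >= 2 sessions", call. = FALSE)
  } else {
    if (is.null(sections) || length(sections) == 0)
      stop("ihc mode requires at least one section", call. = FALSE)
    for (i in seq_along(sections)) {
      s <- sections[[i]]
      if (!is.null(s$ipsi_path) && is.null(s$contra_path))
        stop(sprintf("section %d declares no contralateral partner", i),
             call. = FALSE)
      for (p in c(s$ipsi_path, s$contra_path))
        if (!is.null(p) && !file.exists(p))
          stop(sprintf("section %d: file not found: %s", i, p), call. = FALSE)
    }
  }
  structure(list(mode = mode, spec = spec, sections = sections, cfg = cfg,
                 cfg_plaque = cfg_plaque, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_manifest")
}

#' Read a run manifest from YAML
#'
#' @param path YAML file with fields mode, seed, spec overrides (field_um,
#'   spacing, sessions, ...) and/or sections.
#' @return a `run_manifest`.
#' @export
read_manifest_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(y$spec)) spec <- do.call(scene_spec, y$spec)
  run_manifest(mode = y$mode, spec = spec, sections = y$sections,
               seed = if (is.null(y$seed)) 1L else y$seed,
               out_dir = y$out_dir)
}

provenance_stamp <- function(manifest, stage) {
  sprintf("periprobe-%s|seed=%d|stage=%s",
          as.character(utils::packageVersion("periprobe")),
          manifest$seed, stage)
}

#' Run the longitudinal two-photon pipeline on a synthetic cohort
#'
#' For each hemisphere: builds the scene, renders each session, registers
#' sessions on the vessel channel, segments MX04-labeled deposits, annotates
#' probe distances (ipsilateral), tracks plaques, and computes volume-change
#' series. Produces per-session object tables, track tables, distance-binned
#' counts per timepoint, a size-vs-distance least-squares summary, and the
#' hemisphere x session mixed-design ANOVA on percent volume change.
#'
#' @param manifest a `run_manifest` of mode "longitudinal".
#' @return list: objects, tracks, registrations, bin_counts, size_vs_distance
#'   (slope, r2), anova, provenance. Tables are also written as CSV under
#'   `out_dir` when set.
#' @export
run_longitudinal <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"),
            manifest$mode == "longitudinal")
  spec <- manifest$spec
  cfg <- manifest$cfg_plaque
  ns <- length(spec$sessions)
  all_obj <- list()
  all_tracks <- list()
  regs <- list()
  for (hemi in c("ipsi", "contra")) {
    scene <- tryCatch(build_scene(spec, hemi, granules = FALSE),
                      error = function(e)
                        stop("stage build_scene[", hemi, "]: ",
                             conditionMessage(e), call. = FALSE))
    vessel <- list()
    objs <- list()
    thr_ref <- NULL # day-0 threshold reused across sessions: volume series
                    # need one intensity criterion, not a per-session one
    for (s in seq_len(ns)) {
      chans <- render_session(scene, s, channels = c("mx04", "fitc"))
      vessel[[s]] <- chans$fitc
      filt <- suppress_background(chans$mx04, cfg)
      excl <- if (!is.null(scene$probe)) scene$probe$mask$data != 0 else NULL
      if (is.null(thr_ref)) {
        bin <- threshold_binary(filt, cfg$threshold_k, exclude = excl)
        thr_ref <- attr(bin, "threshold")
      } else {
        bin <- filt$data > thr_ref
      }
      ob <- label_objects(bin, spec$spacing, cfg, intensity = filt$data)
      if (!is.null(scene$dmap)) ob <- object_distances(ob, scene$dmap)
      else { ob$distance_um <- NA_real_; ob$distance_missing <- TRUE }
      ob$session <- s
      ob$day <- spec$sessions[s]
      ob$hemisphere <- hemi
      objs[[s]] <- ob
    }
    reg <- register_sessions(vessel)
    reg$hemisphere <- hemi
    tracks <- match_objects(objs, reg)
    tracks <- volume_change(tracks)
    tracks$hemisphere <- hemi
    tracks$day <- spec$sessions[tracks$session]
    all_obj[[hemi]] <- do.call(rbind, objs)
    all_tracks[[hemi]] <- tracks
    regs[[hemi]] <- reg
  }
  objects <- do.call(rbind, all_obj)
  tracks <- do.call(rbind, all_tracks)
  tracks$track <- paste(tracks$hemisphere, tracks$track, sep = "_")
  rownames(objects) <- rownames(tracks) <- NULL

  # distance-binned counts per timepoint (ipsilateral, 50 um bins)
  ip <- objects[objects$hemisphere == "ipsi" & !objects$distance_missing, ]
  bc <- as.data.frame(table(
    bin = cut(ip$distance_um, seq(0, 300, by = 50), right = FALSE),
    session = ip$session))
  names(bc)[3] <- "count"

  svd_ <- data.frame(
    slope = if (nrow(ip) >= 3)
      unname(stats::coef(stats::lm(volume_um3 ~ distance_um, data = ip))[2])
      else NA_real_,
    r2 = ols_r2(ip$distance_um, ip$volume_um3),
    n = nrow(ip))

  # hemisphere x session ANOVA on percent change (complete tracks only)
  dt <- tracks[!tracks$no_day0 & !is.na(tracks$pct_change), ]
  anova_tab <- NULL
  if (nrow(dt) > 0) {
    des <- data.frame(subject = dt$track, group = dt$hemisphere,
                      within = dt$session, value = dt$pct_change)
    anova_tab <- tryCatch(rm_anova_2way(des), error = function(e) NULL)
  }
  res <- list(objects = objects, tracks = tracks,
              registrations = do.call(rbind, regs),
              bin_counts = bc, size_vs_distance = svd_,
              anova = anova_tab,
              provenance = provenance_stamp(manifest, "run_longitudinal"))
  if (!is.null(manifest$out_dir)) write_bundle(res, manifest$out_dir)
  res
}

#' Run the IHC section pipeline on a synthetic cohort
#'
#' For each section: generates (or loads) the ipsi/contra image pair,
#' computes the background threshold from the contralateral outer annulus,
#' bins intensity concentrically (10 um to 300 um), normalizes to the
#' contralateral average, counts DAPI nuclei in 50 um bins normalized by the
#' contralateral density, aggregates over animals, and tests group
#' differences per bin.
#'
#' @param manifest a `run_manifest` of mode "ihc".
#' @return list: profiles (long), cell_profiles, aggregate, stats, provenance.
#' @export
run_ihc <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"), manifest$mode == "ihc")
  profs <- list()
  cells <- list()
  for (i in seq_along(manifest$sections)) {
    s <- manifest$sections[[i]]
    sec <- generate_ihc_section(
      marker = s$marker, nuclei = s$nuclei,
      img_px = if (is.null(s$img_px)) 1024 else s$img_px,
      noise_sd = if (is.null(s$noise_sd)) 5 else s$noise_sd,
      seed = manifest$seed + 17L * i)
    thr <- background_threshold(sec$contra$marker, sec$center_um, sec$pixel_um)
    pr <- bin_intensity(sec$ipsi$marker, sec$center_um, sec$pixel_um,
                        bin_um = 10, max_um = 300, threshold = thr)
    pr <- normalize_to_contralateral(pr, sec$contra$marker, threshold = thr)
    pr$animal <- s$animal; pr$group <- s$group
    pr$timepoint <- s$timepoint; pr$section <- i
    profs[[i]] <- pr

    ccontra <- count_cells(sec$contra$nuclei, NULL, sec$center_um, sec$pixel_um)
    cd <- sum(ccontra$count) / sum(ccontra$area_mm2)
    cc <- count_cells(sec$ipsi$nuclei, NULL, sec$center_um, sec$pixel_um,
                      contra_density = cd)
    cc$animal <- s$animal; cc$group <- s$group
    cc$timepoint <- s$timepoint; cc$section <- i
    cells[[i]] <- cc
  }
  profiles <- do.call(rbind, profs)
  cell_profiles <- do.call(rbind, cells)
  long <- data.frame(animal = profiles$animal, group = profiles$group,
                     timepoint = profiles$timepoint,
                     bin_start = profiles$bin_start,
                     value = profiles$normalized)
  agg <- aggregate_cohort(long)
  stats_tab <- NULL
  if (length(unique(long$group)) >= 2) {
    des <- data.frame(subject = paste(long$animal, long$group),
                      group = long$group, within = long$bin_start,
                      value = long$value)
    des <- stats::aggregate(value ~ subject + group + within, des, mean)
    stats_tab <- tryCatch(rm_anova_2way(des), error = function(e) NULL)
  }
  res <- list(profiles = profiles, cell_profiles = cell_profiles,
              aggregate = agg, stats = stats_tab,
              provenance = provenance_stamp(manifest, "run_ihc"))
  if (!is.null(manifest$out_dir)) write_bundle(res, manifest$out_dir)
  res
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  summ <- res[!vapply(res, is.data.frame, logical(1))]
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
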