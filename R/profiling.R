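radius_map <- function(dm, center_um, pixel_um) {
  xs <- (seq_len(dm[1]) - 1) * pixel_um - center_um[1]
  ys <- (seq_len(dm[2]) - 1) * pixel_um - center_um[2]
  sqrt(outer(xs^2, ys^2, "+"))
}

#' Background intensity threshold from a reference region
#'
#' `mean + k * SD` of the pixels of `image` lying in the annulus
#' `[r0_um, r1_um)` around `center_um` — by default the unstained margin
#' beyond the tissue disc (320-420 um), which characterizes the noise floor
#' rather than the staining distribution.
#'
#' @param image numeric matrix.
#' @param center_um annulus center (x, y) um.
#' @param pixel_um pixel size um.
#' @param r0_um,r1_um annulus radii um.
#' @param k SD multiplier (default 2).
#' @return scalar threshold.
#' @export
background_threshold <- function(image, center_um, pixel_um,
                                 r0_um = 320, r1_um = 420, k = 2) {
  r <- radius_map(dim(image), center_um, pixel_um)
  v <- image[r >= r0_um & r < r1_um]
  if (length(v) < 2) stop("background annulus contains < 2 pixels", call. = FALSE)
  mean(v) + k * stats::sd(v)
}

#' Concentric radial intensity profile around the probe center
#'
#' Bins pixels into annuli of `bin_um` width out to `max_um` and reports the
#' mean of pixels above `threshold` per annulus. Annuli with no
#' suprathreshold pixel are flagged missing (NA), not zero-filled.
#'
#' @param image numeric matrix.
#' @param center_um probe center (x, y) in um (e.g. the explant hole).
#' @param pixel_um pixel size in um.
#' @param bin_um bin width in um (default 10).
#' @param max_um outer radius in um (default 300); must be a multiple of
#'   `bin_um`.
#' @param threshold background threshold; pixels must exceed it to
#'   contribute (default 0 = all pixels).
#' @return `radial_profile` data.frame: bin_start, bin_end, value, n_pixels
#'   (suprathreshold), area_px (all pixels of the annulus), missing.
#' @export
bin_intensity <- function(image, center_um, pixel_um, bin_um = 10,
                          max_um = 300, threshold = 0) {
  dm <- dim(image)
  if (any(center_um < 0) || center_um[1] > (dm[1] - 1) * pixel_um ||
      center_um[2] > (dm[2] - 1) * pixel_um)
    stop("center is outside the image", call. = FALSE)
  nb <- max_um / bin_um
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin width must divide the maximum radius", call. = FALSE)
  nb <- as.integer(round(nb))
  r <- radius_map(dm, center_um, pixel_um)
  bin <- findInterval(r, seq(0, max_um, by = bin_um),
                      rightmost.closed = FALSE)
  inside <- bin >= 1 & bin <= nb
  above <- inside & image > threshold
  f_all <- factor(bin[inside], levels = seq_len(nb))
  f_sup <- factor(bin[above], levels = seq_len(nb))
  area <- as.integer(table(f_all))
  nsup <- as.integer(table(f_sup))
  val <- rep(NA_real_, nb)
  got <- nsup > 0
  if (any(got)) {
    means <- tapply(image[above], f_sup, mean)
    val[got] <- as.numeric(means[got])
  }
  out <- data.frame(bin_start = seq(0, max_um - bin_um, by = bin_um),
                    bin_end = seq(bin_um, max_um, by = bin_um),
                    value = val, n_pixels = nsup, area_px = area,
                    missing = !got)
  class(out) <- c("radial_profile", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Normalize an ipsilateral profile to the contralateral hemisphere
#'
#' Divides every bin by ONE scalar: the average suprathreshold intensity of
#' the contralateral image (or a precomputed scalar). The scalar is recorded
#' as attribute `contra_mean`.
#'
#' @param profile a `radial_profile` from [bin_intensity].
#' @param contra contralateral image matrix, or a single numeric scalar.
#' @param threshold background threshold applied to the contralateral image.
#' @param eps smallest admissible contralateral average.
#' @return the profile with an added `normalized` column.
#' @export
normalize_to_contralateral <- function(profile, contra, threshold = 0,
                                       eps = 1e-9) {
  cm <- if (is.matrix(contra)) {
    v <- contra[contra > threshold]
    if (length(v) == 0) 0 else mean(v)
  } else as.numeric(contra)
  if (!is.finite(cm) || cm <= eps)
    stop("contralateral average is zero/undefined; cannot normalize",
         call. = FALSE)
  profile$normalized <- profile$value / cm
  attr(profile, "contra_mean") <- cm
  profile
}

#' Detect nuclei in a DAPI channel
#'
#' Background suppression is a light Gaussian subtraction; the image is then
#' thresholded at mean + k*SD and labeled in 2D (8-connectivity); components
#' outside the area gate are discarded.
#'
#' @param nuclei_img numeric matrix (DAPI channel).
#' @param pixel_um pixel size um.
#' @param k threshold SD multiplier (default 2).
#' @param min_area_um2,max_area_um2 nucleus area gate.
#' @return data.frame: id, x_um, y_um, pixels, area_um2.
#' @export
detect_nuclei <- function(nuclei_img, pixel_um, k = 2,
                          min_area_um2 = 10, max_area_um2 = 200) {
  cfg <- filter_config(gaussian_sigma = 30, bp_small = 0.5, bp_large = 30,
                       median_radius = 1, despeckle = FALSE,
                       threshold_k = k,
                       min_voxels = max(1L, floor(min_area_um2 / pixel_um^2)))
  f <- suppress_background(nuclei_img, cfg)
  b <- threshold_binary(f, k)
  obj <- label_objects(b, c(pixel_um, pixel_um, 1), cfg, intensity = f)
  obj <- obj[obj$voxels * pixel_um^2 <= max_area_um2, , drop = FALSE]
  data.frame(id = seq_len(nrow(obj)), x_um = obj$x_um, y_um = obj$y_um,
             pixels = obj$voxels, area_um2 = obj$voxels * pixel_um^2)
}

#' Radial cell-count profile based on DAPI nuclei
#'
#' Cells are nuclei from [detect_nuclei]; a cell is marker-positive when the
#' mean marker intensity inside its nucleus footprint exceeds
#' `marker_threshold`. Counts and densities (per mm^2 of annulus) are binned
#' by nucleus centroid radius. When `contra_density` is supplied, a
#' `normalized` column (density / contralateral density) is added.
#'
#' @param nuclei_img,marker_img matrices sharing geometry (marker may be NULL
#'   to count all nuclei).
#' @param center_um probe center (x, y) um.
#' @param pixel_um pixel size um.
#' @param bin_um bin width um (default 50).
#' @param max_um outer radius um (default 300).
#' @param marker_threshold positivity threshold on mean marker intensity.
#' @param contra_density contralateral count density (cells/mm^2) scalar.
#' @param ... passed to [detect_nuclei].
#' @return `radial_profile` data.frame: bin_start, bin_end, count,
#'   area_mm2, density_per_mm2 (+ normalized).
#' @export
count_cells <- function(nuclei_img, marker_img = NULL, center_um, pixel_um,
                        bin_um = 50, max_um = 300, marker_threshold = 0,
                        contra_density = NULL, ...) {
  if (!is.null(marker_img)) stopifnot(identical(dim(nuclei_img), dim(marker_img)))
  nuc <- detect_nuclei(nuclei_img, pixel_um, ...)
  nb <- as.integer(round(max_um / bin_um))
  r <- radius_map(dim(nuclei_img), center_um, pixel_um)
  bin_area_px <- table(factor(
    findInterval(r, seq(0, max_um, by = bin_um)),
    levels = seq_len(nb)))
  area_mm2 <- as.numeric(bin_area_px) * pixel_um^2 / 1e6
  positive <- rep(TRUE, nrow(nuc))
  if (!is.null(marker_img) && nrow(nuc) > 0) {
    positive <- vapply(seq_len(nrow(nuc)), function(q) {
      i <- round(nuc$x_um[q] / pixel_um) + 1
      j <- round(nuc$y_um[q] / pixel_um) + 1
      hw <- 3
      i0 <- max(1, i - hw); i1 <- min(nrow(marker_img), i + hw)
      j0 <- max(1, j - hw); j1 <- min(ncol(marker_img), j + hw)
      mean(marker_img[i0:i1, j0:j1]) > marker_threshold
    }, logical(1))
  }
  keep <- nuc[positive, , drop = FALSE]
  rr <- sqrt((keep$x_um - center_um[1])^2 + (keep$y_um - center_um[2])^2)
  cts <- table(factor(findInterval(rr, seq(0, max_um, by = bin_um)),
                      levels = seq_len(nb)))
  out <- data.frame(bin_start = seq(0, max_um - bin_um, by = bin_um),
                    bin_end = seq(bin_um, max_um, by = bin_um),
                    count = as.integer(cts), area_mm2 = area_mm2,
                    density_per_mm2 = as.integer(cts) / area_mm2)
  if (!is.null(contra_density)) {
    if (contra_density <= 0) stop("contralateral density must be > 0", call. = FALSE)
    out$normalized <- out$density_per_mm2 / contra_density
  }
  class(out) <- c("radial_profile", class(out))
  out
}

#' Aggregate radial profiles over a cohort
#'
#' Sections within an animal are averaged first (the animal is the
#' experimental unit); then per (group, timepoint, bin) the mean and
#' SEM = SD / sqrt(n_animals) across animals are reported. SEM is NA for a
#' single animal.
#'
#' @param profiles long data.frame with columns animal, group, timepoint,
#'   bin_start, value (one row per section x bin).
#' @return data.frame: group, timepoint, bin_start, mean, sem, n_animals.
#' @export
aggregate_cohort <- function(profiles) {
  stopifnot(all(c("animal", "group", "timepoint", "bin_start", "value")
                %in% names(profiles)))
  per_animal <- stats::aggregate(
    value ~ animal + group + timepoint + bin_start, data = profiles,
    FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  agg <- stats::aggregate(
    value ~ group + timepoint + bin_start, data = per_animal,
    FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v[!is.na(v)]),
                        n = sum(!is.na(v))))
  m <- agg$value
  data.frame(group = agg$group, timepoint = agg$timepoint,
             bin_start = agg$bin_start,
             mean = m[, "mean"],
             sem = ifelse(m[, "n"] > 1, m[, "sd"] / sqrt(m[, "n"]), NA_real_),
             n_animals = as.integer(m[, "n"]))
}
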