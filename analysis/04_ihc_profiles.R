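#!/usr/bin/env Rscript
# Radial intensity and cell-density profiling of synthetic immunostained
# sections with contralateral normalization: a reactive-gliosis-like
# gradient cohort (1 vs 16 weeks) and a neuron-loss cell-count scenario.

suppressPackageStartupMessages(library(periprobe))
dir.create("results", showWarnings = FALSE)

mk_sec <- function(animal, group, tp, marker, dip = 1) list(
  marker = marker, animal = animal, group = group, timepoint = tp,
  nuclei = list(density_per_mm2 = 1200, dip_frac = dip, r0_um = 50,
                radius_um = 3.5, amplitude = 150),
  img_px = 1024, noise_sd = 4)
g1 <- list(baseline = 100, type = "exp", amp = 1.8, decay_um = 75)
g16 <- list(baseline = 100, type = "exp", amp = 3.5, decay_um = 75)
man <- run_manifest("ihc", sections = c(
  lapply(1:3, function(i) mk_sec(paste0("w1_m", i), "wk1", 1, g1)),
  lapply(1:3, function(i) mk_sec(paste0("w16_m", i), "wk16", 16, g16))),
  out_dir = "results/ihc", seed = 4L)
res <- run_ihc(man)
agg <- res$aggregate
near <- agg[agg$bin_start == 0, ]
cat(sprintf("normalized intensity in the 0-10 um bin: wk1 %.2f, wk16 %.2f\n",
            near$mean[near$group == "wk1"], near$mean[near$group == "wk16"]))
cat("group x bin ANOVA:\n"); print(res$stats)
write.csv(agg, "results/ihc_aggregate.csv", row.names = FALSE)

# neuron-loss style cell counting, 50 um bins
secs <- lapply(1:6, function(s) generate_ihc_section(
  marker = list(baseline = 100, type = "flat"),
  nuclei = list(density_per_mm2 = 2000, dip_frac = 0.5, r0_um = 50,
                radius_um = 3.5, amplitude = 150),
  noise_sd = 3, seed = 700 + s))
norm_bins <- sapply(secs, function(sec) {
  ccon <- count_cells(sec$contra$nuclei, NULL, sec$center_um, sec$pixel_um)
  cd <- sum(ccon$count) / sum(ccon$area_mm2)
  count_cells(sec$ipsi$nuclei, NULL, sec$center_um, sec$pixel_um,
              contra_density = cd)$normalized
})
cells <- data.frame(bin_start = seq(0, 250, 50), bin_end = seq(50, 300, 50),
                    normalized_density = rowMeans(norm_bins),
                    sem = apply(norm_bins, 1, sd) / sqrt(ncol(norm_bins)))
write.csv(cells, "results/cell_density_profile.csv", row.names = FALSE)
print(cells)
cat("The depleted 0-50 um core reads ~0.5 of the contralateral density;",
    "the periphery returns to ~1.\n")
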