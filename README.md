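# periprobe

Quantification of age- and disease-associated tissue responses around
chronically implanted intracortical microelectrodes, from multiphoton
z-stacks and immunostained sections.

Chronic electrode implantation perturbs the surrounding cortex: in aged and
Alzheimer's-model mice, autofluorescent lipofuscin granules and
methoxy-X04-labeled amyloid deposits accumulate preferentially near the
shank, pre-existing plaques near the implant stop growing while distal
plaques keep growing, and glial/neuronal markers show radially decaying
changes around the insertion site. `periprobe` implements the measurement
pipeline behind those observations, for users analyzing such experiments or
benchmarking analysis choices on simulated ground truth:

* **Distance-map referencing** — a 2D electrode footprint is rotated to the
  insertion angle (default 30°) and expanded into an exact anisotropic 3D
  Euclidean distance map `D(v) = min_m ||x_v − x_m||` (µm), so every
  segmented object gets its nearest distance to the electrode surface.
* **Segmentation** — Gaussian-subtraction background removal (σ = 20 px),
  difference-of-Gaussians bandpass, median + despeckle, binarization at
  `mean + 2.5 SD`, 3D connected components. Lipofuscin is detected by its
  1:1 intensity across the green and red emission channels (per-voxel ratio
  within `[1/(1+tol), 1+tol]`, both channels suprathreshold); amyloid
  deposits from the MX04 channel; 2D plaque areas from stained sections.
* **Longitudinal tracking** — sessions are registered by normalized
  cross-correlation of the vasculature channel (sub-voxel), plaques linked
  by greedy nearest-centroid matching, and per-track series
  `%Δv(t) = 100·(v(t) − v(0))/v(0)` computed.
* **Radial profiling** — mean suprathreshold intensity in 10 µm annuli and
  DAPI-based cell densities in 50 µm annuli out to 300 µm from the probe
  center, each normalized by a single scalar from the contralateral (intact)
  hemisphere; cohort aggregation as mean ± SEM with the animal as the
  experimental unit.
* **Statistics** — mixed-design (two-way repeated-measures) ANOVA with
  Greenhouse–Geisser correction, Bonferroni-adjusted post-hoc t-tests, and
  Welch's t-test.
* **Synthetic data** — a seeded generator (`scene_spec()`, `build_scene()`,
  `render_session()`, `generate_ihc_section()`) produces every input with
  known ground truth: exponentially probe-enriched granule fields,
  hemisphere-specific plaque growth, vessel landmarks, session drift,
  radial marker profiles and nuclei fields.

## Worked example

Simulate a two-hemisphere plaque cohort (25 ipsilateral plaques with 0%
growth per session, 27 contralateral with +8% volume growth per session,
seven imaging sessions over 12 weeks, ≤10 µm session drift) and run the
longitudinal pipeline:

```r
library(periprobe)

spec <- scene_spec(
  field_um = c(158.975, 158.975, 125),
  probe = list(width_um = 40, thickness_um = 15, length_um = 240,
               angle_deg = 30),
  seed = 11L)
res <- run_longitudinal(run_manifest("longitudinal", spec = spec, seed = 11L))

ns <- length(spec$sessions)
term <- res$tracks[res$tracks$session == ns & !res$tracks$no_day0, ]
tapply(term$pct_change, term$hemisphere, mean)
#>     contra       ipsi
#>  56.772672   0.369724
res$anova
#>         effect df1 df2        F             p          p_gg
#> 1        group   1  50 3738.611  1.162270e-48            NA
#> 2       within   6 300 3028.033 4.468613e-265 1.221032e-169
#> 3 group:within   6 300 2755.461 4.888122e-259 8.478668e-166
```

All 52 seeded plaques are tracked across all seven sessions. The intact
hemisphere's mean terminal percent change (+56.8%) recovers the generated
+58.7% truth; the implanted hemisphere stays flat (+0.4% vs 0 truth); and
the hemisphere × session interaction — the signature of implantation
halting local plaque growth — is detected by the mixed-design ANOVA.

The numbered scripts under `analysis/` run the full study workflow:
`01_simulate_scenes.R` (scenes + ground truth), `02_granule_recovery.R`
(lipofuscin detection and distance profiles; on the default scene it
detects 194 of 200 granules with 0.55-voxel centroid RMS and Spearman ρ = 1
against the truth distance profile), `03_plaque_tracking.R` (the run
above), `04_ihc_profiles.R` (radial intensity and cell-density profiles;
a 50%-depleted 0–50 µm core reads 0.58 ± 0.10 of the contralateral
density). Tables land under `results/`.

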