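---
title: "Quantifying tissue responses around chronic brain implants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue responses around chronic brain implants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periprobe)
```

## The problem

Chronically implanted intracortical microelectrodes provoke a local tissue
response — gliosis, altered protein clearance, and, in aged or
Alzheimer's-model brains, accelerated accumulation of age- and
disease-associated aggregates (lipofuscin, amyloid plaques, phospho-tau).
Quantifying these effects requires measuring *where* things are relative to
the electrode surface and *how* they change over months of implantation.
`periprobe` implements that measurement pipeline end to end:

1. an anisotropic 3D Euclidean distance map of the electrode surface, built
   from a 2D footprint mask rotated to the insertion angle;
2. segmentation of lipofuscin granules (dual-channel 1:1 autofluorescence)
   and methoxy-X04-labeled amyloid deposits (filter chain + intensity
   threshold + 3D connected components);
3. longitudinal registration on the vasculature channel and plaque tracking
   with volume-change series;
4. concentric radial profiling of stained sections (intensity every 10 µm,
   cell counts every 50 µm, out to 300 µm) normalized to the contralateral
   hemisphere;
5. the inferential layer: mixed-design (two-way repeated-measures) ANOVA,
   Bonferroni post-hoc t-tests, and Welch's t-test.

Because no real imaging data ship with the package, a first-class synthetic
generator (`scene_spec()`, `build_scene()`, `render_session()`,
`generate_ihc_section()`) produces every input with known ground truth, and
all validation is parameter recovery against that truth.

## The distance map

The electrode footprint is a 2D binary mask. `rotate_footprint()` embeds it
as a plate of configurable thickness and rotates it about the image-x
(medio-lateral) axis, so the shank descends through the stack at the
insertion angle (default 30°, within the 25–30° range typical of these
implants); resampling is nearest-neighbor because that preserves binarity —
linear interpolation plus re-thresholding changes the mask volume.
`compute_distance_map()` runs an exact separable parabolic-envelope
Euclidean distance transform with per-axis physical spacing (default
0.621 × 0.621 × 2.5 µm), so distances are in micrometers and correct under
anisotropy. Distances are voxel-center to voxel-center; sub-voxel surface
accuracy is out of scope. The transform is validated against an O(n²)
brute-force nearest-mask-voxel search, exactly, on randomized anisotropic
masks.

Object-to-probe distance (`object_distances()`) is the map value at the
voxel nearest the real-valued centroid, with ties between voxel centers
resolved toward the lower index; out-of-bounds centroids are flagged, never
silently dropped.

## Segmentation

The background-suppression chain (`suppress_background()`) follows, per
z-slice: subtraction of a Gaussian-blurred copy (sigma = 20 px), a bandpass
implemented as a difference of Gaussians, a median filter, and a 3×3-median
despeckle. The bandpass is parameterized by *structure sizes* in pixels and
maps size `s` to a Gaussian sigma of `s/2`. Two scale choices matter:

* **Granule-scale config (default)** passes structures of 1–20 px. Granules
  are ~4–10 px across and ride through unattenuated.
* **Plaque-scale config** (`filter_config(bp_large = 64)`) passes 1–64 px.
  A 20 px upper scale sits at the plaque radius and attenuates large plaques
  more than small ones; that scale-dependent shaving biases longitudinal
  volume-change series downward, so the longitudinal pipeline uses the wider
  passband for MX04 deposits. Both configs are user-settable.

Binarization (`threshold_binary()`) is `mean + 2.5 SD` over the filtered
volume, excluding electrode-mask voxels, with a strict `>`; a zero-variance
image yields an empty mask by convention. For longitudinal series
`run_longitudinal()` derives this threshold once, at the reference (day 0)
session, and applies it to every later session: a per-session threshold
rises as plaques grow (objects inflate the volume mean and SD), which
systematically erodes later volumes; a volume-change series needs one
intensity criterion.

Connected components are labeled in 3D (default 26-connectivity; 8 in 2D)
and components under 10 voxels are discarded. The default was chosen
because two successive 3×3 median passes leave the noise field laterally
correlated over roughly a 3-px grain, so ~5-voxel suprathreshold patches
arise from noise alone even after dual-channel gating; 10 voxels is also
about the smallest physically plausible granule (~2.7 µm diameter) at the
default sampling. Both the minimum size and the connectivity are
configurable.

Lipofuscin (`detect_lipofuscin()`) exploits its hallmark equal-intensity
autofluorescence across the green and red emission channels: candidate
voxels must be suprathreshold in *both* channels and show a red/green ratio
within `[1/(1+tol), 1+tol]` after normalizing each filtered channel to its
mean. The tolerance default 0.25 operationalizes the qualitative "1:1"
criterion; a tolerance of zero admits nothing once noise is present, since
exact equality has measure zero. Spectral bleed-through is handled, when
needed, by `unmix_channels()`, a per-voxel linear solve against a known
mixing matrix (negative solutions clipped to zero and the clipped fraction
reported) — a documented linear stand-in for dedicated unmixing tools,
whose internals are out of scope.

## Longitudinal tracking

`register_sessions()` estimates a per-session rigid translation by
FFT-based normalized cross-correlation of the mean-subtracted vessel
channel against the reference session, refined to sub-voxel precision by
separable quadratic peak interpolation; scores below 0.3 are flagged
low-confidence. Translation-only registration reflects the acquisition
protocol, where each session re-finds the same field using the vasculature
as a landmark; deformable alignment is out of scope.

`match_objects()` links drift-corrected centroids session-to-session,
closest pair first, each object used at most once, pairs beyond 20 µm left
unmatched; unmatched objects start new tracks, and a track absent for at
most one session can be re-linked (gap bridging) before it terminates. The
greedy rule is validated in tests against an exhaustive minimal-total-
distance assignment. `volume_change()` reports Δv(t) = v(t) − v(0) and
percent change 100·(v(t) − v(0))/v(0); tracks with no day-0 observation are
excluded from the percent series (flagged, delta retained).

## Radial profiling of sections

`bin_intensity()` bins pixels into concentric annuli (10 µm wide to 300 µm)
around a user-supplied probe center — the explant hole in a real section;
automatic detection is out of scope — and reports the mean of pixels above
a background threshold per annulus; empty annuli are flagged missing, not
zero-filled. The threshold is `mean + 2 SD` of a designated background
region. By default that region is the unstained margin beyond the tissue
(320–420 µm from the center): deriving it from an annulus *inside* stained
tissue would place the cut above the staining baseline and truncate the
intensity distribution, breaking the linearity of the contralateral
normalization (a 2× step would read ~1.8). The region is configurable, and
it is taken from the contralateral image for stability.

`normalize_to_contralateral()` divides every bin by a *single scalar* — the
average suprathreshold intensity of the contralateral (intact) hemisphere
image — so a section identical to its contralateral partner normalizes to
exactly 1 in every bin.

`count_cells()` detects DAPI nuclei (light background suppression,
`mean + 2 SD` threshold, 2D labeling, 10–200 µm² area gate), calls a cell
marker-positive when the mean marker intensity over the nucleus footprint
exceeds the marker threshold, bins counts every 50 µm, and reports
densities per mm² of annulus so differing usable areas compare fairly;
normalization again uses the contralateral density as one scalar.

`aggregate_cohort()` averages sections within an animal first — the animal
is the experimental unit; pooling sections would pseudo-replicate — then
reports mean ± SEM (SD/√n animals) per group × timepoint × bin.

## Statistics

`welch_t()` is the unequal-variance t-test with Welch–Satterthwaite degrees
of freedom (two zero-variance samples with equal means return t = 0, p = 1).
`rm_anova_2way()` fits the mixed design — one between-subjects factor
(group or hemisphere), one within-subjects factor (timepoint or bin) — with
the subject stratum as the error term for the between effect and the
within × subject residual for the within and interaction effects ("two-way
repeated-measures ANOVA" with a between factor is formally this mixed
design). Subjects missing any within level are dropped and recorded. With
more than two within levels a Greenhouse–Geisser corrected p-value is
reported alongside the uncorrected one, since sphericity is not guaranteed.
`bonferroni_posthoc()` runs the pairwise t-tests (paired for within-factor
contrasts, unpaired otherwise) and adjusts by `min(1, m·p)` over the whole
family. Units are whatever the caller passes as subjects — plaque-level and
animal-level analyses are both possible; plaque-level treats correlated
plaques within an animal as independent, which the caller should weigh.

## The synthetic generator

The generator's defaults encode the emulated acquisition: 635.9/1024 µm
lateral pixels, 2.5 µm axial step (midpoint of the 2–3 µm protocol range),
a 30° shank, seven sessions spanning 12 weeks (days 0–84 every 14), and
Poisson shot noise plus Gaussian read noise on top of a constant background
offset — a generic two-photon noise model, since no noise model is
published for these data. Signal amplitudes are set via SNR = peak object
amplitude over background noise SD (granules 5, plaques and vessels 10).

Truth objects are spheres: spheres make volume truth exact and recovery
testable, which is the point of the generator — the acceptance surface is
parameter recovery, not visual realism. Granules follow an inhomogeneous
point process with intensity `baseline + amplitude·exp(−d/decay)` around
the probe (defaults 2 000/mm³ baseline, 50 000/mm³ amplitude, 50 µm decay,
200 granules conditioned per scene; log-normal radii, median 2.5 µm,
σ_log 0.25 — granule SNR and size ranges are not published, so these are
stated choices, not fits). Plaques (25 ipsilateral / 27 contralateral,
radii 5–10 µm, ≥30 µm apart) grow multiplicatively in volume per session
(ipsi 0%, contra +8%). A fixed seeded set of bright tubes serves as the
vasculature landmark, reused across sessions. Inter-session drift is a
reflected random walk capped at ±10 µm laterally (±2.5 µm axially): sessions
are re-found on the vasculature, so drift must not accumulate without
bound — and the placement margins include the cap so every truth object
stays inside the field in every session, which keeps the generator's
conservation invariant (all truth objects appear in a noiseless render).

Synthetic sections place the stained tissue on a disc (radius 310 µm)
surrounded by an unstained margin; marker profiles are flat, step, or
`1 + (amp−1)·exp(−r/decay)` around the center, and nuclei are disks at a
radial density with an optional depleted core. The contralateral partner is
rendered from the distance-independent baseline parameters only.

What the generator does *not* emulate: irregular object morphology, glial
process texture, optical-window degradation, depth-dependent attenuation,
and spectral bleed-through beyond one linear mixing matrix. Passing the
recovery suite therefore shows the pipeline is correct and unbiased under
its stated model, not that it is robust to every property of real tissue.

## Problem sizes and numerical choices

The validation suite uses a 512 × 512 × 100-voxel granule scene (the full
emulated field of view at native sampling), 256 × 256 × 50-voxel tracking
scenes over seven sessions and both hemispheres, and 1024 × 1024 sections —
sizes chosen so the whole suite completes on a single CPU in minutes while
keeping object sampling at the native resolution. Degenerate inputs are
defined, not errors, where a convention exists (constant image → empty
threshold mask; empty mask → empty object list; identical samples → t = 0,
p = 1); they are errors where no sensible result exists (empty electrode
mask, singular mixing matrix, all-zero vessel channel, contralateral
average of zero). Ties in the centroid-to-voxel lookup round toward the
lower index, documented and tested. All randomness flows from integer
seeds; identical spec + seed is bit-identical everywhere downstream, which
the tests assert by serializing entire result bundles.

## Known limitations

* Volumes are suprathreshold voxel counts; a PSF-plus-threshold halo of a
  few tenths of a micrometer inflates every radius slightly. The bias mostly
  cancels in percent-change series (the terminal percent change of the
  +8%/session cohort is recovered within ~2 points) but absolute volumes
  carry it.
* Greedy matching is not globally optimal; it agrees with exhaustive
  assignment in the regimes tested (object spacing ≫ residual drift) but
  dense fields with large drift would need a global matcher.
* The mean + k·SD threshold statistics are computed per volume, not per
  slice; with strong depth-dependent attenuation (not modeled here) a
  per-slice variant could behave differently.
* Plaque splitting/merging events are not modeled or tracked.
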