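---
title: "Quantifying cancer-cell implantation and invasion in peritoneal explants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cancer-cell implantation and invasion in peritoneal explants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritoscore)
```

## The measurement problem

Ex vivo peritoneal explant co-cultures measure the early peritoneal
metastatic cascade: dye-stained cancer cells must detach, survive in
suspension, reach the explanted peritoneum, attach to its mesothelial
monolayer, and invade into the submesothelial tissue. Two readouts
summarize the outcome per explant, per day:

* **Implantation score** — how efficiently suspended cells become
  tissue-associated. Random 583 × 583 µm fields of the explant are
  imaged as confocal z-stacks (2 µm steps, 50–75 µm total depth); the
  red (tracker dye) channel is collapsed into an en-face maximum
  projection and cells are counted. The mean count per field is scaled
  to the whole 1.5 × 1.5 cm explant — `round((15000/583)^2) = 662`
  squares — and divided by the number of live cells available in
  suspension on Day 1:

  $$\mathrm{Implantation} = \frac{\bar{c}\,\times\,662}{N_\mathrm{live}}$$

  This normalization matters whenever a perturbation (e.g. restoring an
  adhesion protein) changes how many cells are alive and suspended in
  the first place.

* **Invasion score** — how deep cells penetrate past the mesothelial
  surface. In the reconstructed 3D stack, each cell's depth is the
  axial distance from the mesothelial surface to the cell's mid-point.
  Per field the three deepest cells are averaged; per sample the five
  field values are averaged; replicate measurements ("observers") are
  averaged into the final score, in µm.

This package implements the full measurement chain on synthetic imaging
with planted ground truth, so every stage can be validated against
known answers before being pointed at real data.

## Pipeline stages and their models

### Synthetic stacks (`generate_stack()`)

The generator emulates the imaging physically enough to exercise every
downstream stage:

* **Geometry.** 583 µm square fields on a 512-px lateral grid
  (1.139 µm/px — the same grid that, resampled orthogonally, yields 512
  slices 1.14 µm apart), z-planes every 2 µm from the objective-proximal
  face (`z = 0`) down to 60 µm. The z-grid convention is
  `0, 2, …, 60` → 31 planes. The mesothelial surface is the smallest-z
  tissue boundary, matching imaging from beneath a floating explant.
* **Cells.** Isotropic 3D Gaussian blobs, σ = radius/2 with a 7 µm
  default radius; peak amplitude is `snr` × background noise sd. Depths
  below the surface default to an exponential distribution
  (penetration over the assay's time frame is shallow), truncated so
  blobs stay inside the imaged depth. Placement enforces a minimum
  pairwise *lateral* distance, since lateral separation is what keeps
  blobs distinct in the en-face projection.
* **Tissue.** The green channel carries collagen reflectance: a
  positive textured field (mean 50 counts, sd 15, 5 µm correlation
  length) present only at and below the surface. `coverage < 1`
  removes reflectance from smooth random patches, emulating the patchy
  mesothelium of late-day explants. Surface models are a tilted plane
  or a smooth low-order "sheet" of random cosine modes.
* **Noise.** Poisson shot noise on signal plus baseline, plus Gaussian
  read noise (sd 3 counts on baselines of 10 red / 2 green), rounded to
  integer detector counts and clamped at zero. The dye's persistence
  over several divisions is modelled only as optional per-day growth of
  the implanted-count expectation in `generate_experiment()`, not as
  intensity decay.

What the generator deliberately does **not** model: the optical PSF,
photobleaching, red/green bleed-through, mesothelial-cell rendering,
autofluorescent debris, or tissue deformation. Passing tests therefore
demonstrate that the measurement chain is correct *given* blob-like
cells on a textured reflectance background — not that detection is
robust to every artifact of real microscopy; on real data the detector
threshold and radius remain the operator's responsibility.

### Spot detection (`detect_spots_2d()`, `detect_spots_3d()`)

Counting uses a scale-matched Laplacian-of-Gaussian (LoG) detector —
the same family as the interactive tool the assay was designed around —
with strict local maxima and greedy non-maximum suppression at
1.5 × radius. Design choices that needed deciding:

* **Response normalization.** The raw LoG response is divided by the
  response of an ideal unit-peak matched blob, so thresholds are in
  intensity units: a matched blob of peak amplitude A scores ≈ A.
* **Anisotropy.** The axial kernel is scaled by dz/dy (2 µm z-steps vs
  1.14 µm pixels), per axis, in pixels.
* **Median prefilter.** A 3 × 3 lateral median runs first. Shot noise
  has a heavy upper tail, and the maximum projection keeps every
  voxel's excursions; single-voxel spikes otherwise dominate the null
  extremes of the response.
* **Automatic threshold.** `auto_factor` × the robust background sd
  (MAD) of the (prefiltered) input — 12 in 2D, 16 in 3D. The factors
  were calibrated on pure-noise simulations of the generator's noise
  model: spurious maxima stay below ~7× (2D) / ~10× (3D) MAD, while
  blobs at the assay's design SNR of 10 respond above ~21× / ~24×, so
  the defaults sit near the geometric midpoint, a ~1.5× margin each
  way. At SNR 2 recall degrades (faint cells are missed) but precision
  holds — the documented operating curve. On real data the threshold
  should be set from a control field, exactly as with interactive
  tools.
* **Borders.** Spots within one radius of the field border are kept —
  counts are densities per field, and excluding them would bias small
  fields. The single outermost pixel ring is excluded from candidate
  maxima, because replicate padding inflates both the median filter
  and the LoG response exactly there; a genuine near-border cell still
  peaks off that ring.
* **Localization.** Sub-voxel positions come from a three-point
  quadratic fit along each axis; a spot's `z_um` is the operational
  "mid-point of the cell".

### Surface estimation (`estimate_surface()`)

The mesothelial reference surface is defined operationally as the
*reflectance onset*: per lateral column (block-averaged to ~9 µm for
noise suppression), the first z at which the 3-plane axially smoothed
green profile crosses 50% of that column's robust maximum (95th
percentile), refined by linear interpolation between planes. All
criteria are relative, so the map is invariant to uniform intensity
rescaling. Columns whose robust maximum falls below 30% of the field's
high-reference (95th percentile of column maxima) are deemed
unconfident — their fraction is reported as `coverage` — and are filled
from a global plane fit, then blended with confident columns by
confidence-weighted Gaussian smoothing at 20 µm. If coverage drops
below 20%, the global plane alone is used: late-day explants with a
degraded mesothelium still need a reference. Whether a human observer
would draw the reference at the reflectance onset or at the visible
mesothelial cells is unknowable from the assay description; the onset
is the reproducible operationalization.

### Scoring (`field_invasion()`, `sample_invasion()`, `implantation_score()`)

* Depth is the **axial** (z) distance from the surface, matching a
  measurement made on an orthogonal slice; the 3D Euclidean distance to
  the surface sheet would differ only on steep surfaces and is noted as
  the alternative.
* A detected cell *above* the estimated surface gets depth 0
  (surface-adherent) rather than being excluded — exclusion would bias
  counts and the k-deepest statistic.
* Fields with fewer than 3 cells average what is there and carry a
  `short_field` flag; empty fields are missing and are dropped from the
  5-field mean (flagged `incomplete`).
* Each unique detected cell is scored once; scrolling through
  overlapping orthogonal views could double-count a cell, which is why
  scoring works from the deduplicated 3D spot list.
* `combine_observers()` generalizes two-observer averaging to any
  number of measurement replicates and records the max–min
  disagreement. The automated pipeline is one observer.
* 662 is computed, not hard-coded: `squares_per_explant(15000, 583)`.
  The Day-1 live suspension count divides all days of a sample, since
  the denominator is measured once, before the explant is washed.

### Group statistics (`compare_arms()`)

Per day and arm pair: group means, SEMs and a two-sided Welch t-test;
Bonferroni adjustment `min(1, m·p)` over the family of all day-wise
pairwise comparisons within one metric (the family is configurable —
the assay description does not state one); plus a per-metric one-way
ANOVA across arms. Two identical constant groups are reported as
p = 1. Days with a single replicate in either arm are skipped with a
warning rather than silently tested.

## Numerical choices and degenerate inputs

* Stacks are stored as multi-page TIFF with a JSON sidecar carrying
  channel order, voxel sizes, and a power-of-two intensity scale.
  16-bit storage round-trips integer count grids bit-exactly (counts
  below 32768); 32-bit mode stores general non-negative float grids on
  a 2^32−1 quantization grid, exact when the data's dynamic range is
  within 2^9 of its maximum. Reading a stack without voxel-size
  metadata is a hard error: every downstream quantity is in µm.
* Tie-breaking: plateau local maxima keep the smallest linear index;
  sub-voxel offsets are clamped to ±0.5 voxel; onset crossings clamp
  their interpolation fraction to [0, 1].
* Empty cases: blank images give zero spots (the auto threshold is
  floored above zero); zero-cell fields give a missing invasion score;
  all-missing samples give a missing sample score; an empty score set
  is an error.
* Seeds: one master seed fans out via
  `seed_i = (seed × 1000003 + i) mod (2^31 − 1) + 1`, so stacks,
  experiments and stages are individually reproducible, bit-for-bit.

## Problem sizes used by the test suite

The package's own validation uses: 50 default-geometry fields
(512 px × 31 planes) for detector/scoring oracle equivalence; a two-arm
experiment of 3 samples × 5 fields per arm at Day 1 (30 stacks) for
effect recovery — the arm contrast (implantation probability 0.4 vs
0.1, depth means 25 vs 8 µm) is chosen to mirror the direction of an
adhesion-restoration rescue; 100 + 100 reduced-geometry fields (96 px)
for the detector operating curve at SNR 10 and SNR 2; and three
default-geometry fields (flat, tilted, 30%-patchy) for surface
recovery. Module tests run on 128-px fields with the same voxel sizes.

## Known limitations

* The detector is tuned for near-uniform cell sizes (one LoG scale); a
  multi-scale extension would be needed for strongly heterogeneous
  morphologies.
* Touching or laterally overlapping cells merge in the projection and
  count as one; the assay's cell densities make this rare, but dense
  clusters (e.g. proliferating colonies at late days) would need
  segmentation rather than spot counting.
* The surface estimator assumes reflectance begins *at* the surface;
  sub-surface voids or strongly scattering debris above it would bias
  the onset.
* Wound-area segmentation from images is a deliberately simple
  threshold heuristic (`wound_area_estimate()`), provided for synthetic
  demonstrations; quantitative scratch-assay analysis should supply
  measured areas to `percent_healed()`.
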