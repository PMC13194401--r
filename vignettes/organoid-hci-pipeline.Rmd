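---
title: "Quantifying 3D organoid-immune co-culture screens from high-content images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D organoid-immune co-culture screens from high-content images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidhci)
```

## The assay and what the package measures

Immuno-oncology screens increasingly use 3D co-cultures: patient-derived
organoids (or minimally processed fresh tumor tissue, the *ex vivo* patient
tissue — EVPT — variant) are embedded in a hydrogel in 384-well plates,
optionally together with immune effector cells, exposed to therapeutics, and
imaged as multi-channel confocal z-stacks. Wells are seeded with on the order
of 50–300 multicellular clusters of 50–200 µm diameter; stacks cover the gel
with 20–80 optical sections at a 20–50 µm z-step. Three channels carry the
information: a nuclear stain, an F-actin stain outlining cell bodies and
multicellular structures, and (in co-culture variants) a cell-tracker dye
pre-loaded into the immune cells.

`organoidhci` turns those stacks into the screen's readouts:

* **tumoroid (multicellular object) count** per well,
* **cumulative tumoroid volume** per well (the response proxy),
* **single-cell count** (cells outside multicellular objects, including the
  immune fraction),
* **immune infiltration** — tracker-labeled cells located inside
  multicellular objects,

followed by the screen-level machinery: per-well image QC, the control-window
gate, percent-of-control (poc) normalization, technical-replicate
aggregation, response categorization, and ANOVA with Tukey or Dunnett
post-hoc comparisons.

## Object definition and segmentation

A multicellular object is an intact actin structure containing nuclei. The
segmentation is deliberately classical, fully parameterized in
`default_config()$segmentation`, and identical for every well:

1. anisotropic Gaussian smoothing (σ = 5 µm per axis, divided by the voxel
   spacing — at a 25 µm z-step this correctly applies almost no axial
   smoothing);
2. a global Otsu threshold over the smoothed actin channel, floored at
   background + 5 robust standard deviations so an empty well yields an
   empty labeling rather than a noise split;
3. per-slice morphological closing (disc radius 2 px) and per-slice hole
   filling;
4. 26-connected 3D components; components smaller than a 15 µm sphere are
   discarded as debris.

Nuclei and tracker cells use the same detector family: smoothing, median
background subtraction, an Otsu threshold floored at 8 background SDs, and
3D local-maximum seeding with a minimum separation of one nucleus diameter
(10 µm). Two blobs closer than the separation merge into one detection; this
is the documented behavior, not an error.

An actin component is *multicellular* iff its equivalent spherical diameter
is ≥ 30 µm **and** it contains ≥ 2 nucleus centroids; the nucleus rule
dominates, so a 60 µm blob with one nucleus counts as a single cell. Every
detected nucleus is assigned exactly once (single cells + nuclei inside
multicellular objects = all detected nuclei), an identity the test suite
checks exactly. The 30 µm single-cell cut-off is this package's declared
default — the platform the design follows does not publish its value.

Fused structures are *not* split (no watershed): two touching tumoroids
measure as one object, which is why the synthetic generator keeps a
clearance between seeded clusters (below).

## Morphometry

Per object the package reports per-slice cross-sectional areas (µm²,
voxel-counted), the volume as the cumulative area through the stack times
the z-step, the equivalent spherical diameter `(6V/π)^(1/3)`, the contained
nucleus count, and the infiltrated-cell count (tracker centroids inside the
object mask — centroid-in-mask, not partial overlap). Per well these
aggregate to the object count, total volume (mm³; 1 mm³ = 10⁹ µm³, an exact
conversion), mean/median object volume, single-cell count and infiltration
fraction. Note that summing voxel-counted slice areas times the z-step is
algebraically identical to voxel-count volume, so no separate "voxel mode"
exists.

## Quality control

* **Control window**: a control well passes iff it has ≥ 50 multicellular
  objects *and* ≥ 0.01 mm³ cumulative volume (both inclusive). Without that
  window, a volumetric reduction cannot be read as a response. The per-well
  gate is applied to every control well; the sample fails when more than
  half of its control wells fail (the fraction is configurable — whether the
  gate applies per well or to a control summary is a design choice this
  package makes explicitly).
* **Image QC**: wells are excluded for empty/weak staining, debris
  overgrowth (foreground fraction outside [1e-4, 0.5]), weak labels
  (median foreground < 2× background), or a segmentation that does not
  represent the image (< 80% of bright actin voxels inside the final
  masks). Background is estimated from the lower quartile and noise from
  the MAD so the estimates survive saturated wells. On healthy plates the
  exclusion fraction stays well under the 4%-of-wells warning level.
* **Replicate precision**: the CV (sample SD / mean, n−1 denominator — the
  denominator is a declared choice) of total volume per replicate group;
  well-behaved models stay below 0.35.
* **Edge effects**: edge-ring vs interior control wells by two-sided
  Wilcoxon rank-sum; flagged only when p < 0.01 *and* the median ratio falls
  outside [0.8, 1.25]. The test and its cutoffs are this package's
  construction (the practice it follows states the check, not the method);
  fewer than 3 wells on either side yields "not evaluable".

## Normalization, categories, statistics

Per sample, each readout is normalized as `poc = 100 · value /
mean(passing control wells)` (mean chosen so control poc averages exactly
100; a median denominator is available). Technical replicates aggregate by
the convention: median for total volume and object count (robust to a
single outlier well in heterogeneous tissue), mean for single-cell count and
infiltration. The volume reduction `100 − poc` maps onto response categories
`<10` (non-responder), `10–30`, `31–50`, `51–70`, `>71`. The printed labels
leave (30, 31) etc. undefined on a continuous scale; the package resolves
them as half-open bins at 10/31/51/71, which preserves the labels and covers
the whole line.

Group comparisons run a fixed-effects ANOVA on well-level poc with Tukey HSD
(all pairs) or Dunnett (many-to-one vs a named control) adjustment —
`stats::aov`/`TukeyHSD` and `multcomp` under the hood — with significance
stars at 0.05/0.01/0.005/0.0001. The test suite checks the one-way
F statistic and Tukey p-values against explicit sums-of-squares formulas and
verifies ~5% type-I error on null simulations. Dose series are flagged for
monotone trends by the sign of the Spearman correlation (|ρ| ≥ 0.8 by
default).

## The synthetic plate generator

No imaging data are deposited for assays of this kind, so the package ships
a generator that produces wells with exact ground truth; it is first-class,
tested code and the basis of every end-to-end check.

A scene draws a tumoroid count uniformly from 50–300 (per `sample_scene()`
call; on a simulated plate, wells of one sample share a seeding intensity —
one suspension is dispensed across the plate — with per-well Poisson
variation), diameters from a log-normal (median 90 µm, σ_log 0.4) truncated
to (50, 200) µm, and places the spheres without overlap, largest first, with
a 25 µm minimum clearance. The clearance reflects clusters dispersing in the
gel; it also keeps distinct seeded clusters resolvable by a segmenter that
deliberately never splits fused objects. Nuclei fill each body on a jittered
3D grid at 20 µm spacing (a cheap blue-noise stand-in for Poisson-disc
sampling). Free single cells are Poisson (mean 300). In co-culture mode,
labeled effector cells are added at an E:T ratio of 5 per tumoroid-resident
cell, of which 10% appear in the imaged gel volume
(`labeled_fraction_in_field`; effectors are pipetted on top of the gel, and
the in-field mapping is otherwise unspecified).

A treatment effect is applied analytically: volumes scaled by
`1 − volume_reduction_fraction` (diameters by its cube root, nuclei
following the shrinking body), a Bernoulli subset of tumoroids removed,
labeled cells placed inside surviving tumoroids with probability
`infiltration_rate`, and the single-cell count rescaled. The effect
uniforms are always drawn in the same order, so scenes with the same seed
and different effect strengths are coupled: the null effect reproduces the
control scene bit-for-bit and total true volume is exactly monotone in both
fractions.

Rendering uses voxel-center geometry on a (y, x, z) grid: filled spheres in
the actin channel (uniform 2000 ADU over a 100 ADU background), thin actin
shells around single cells, Gaussian blobs (σ = 4 µm, peak 3000 ADU) for
nuclei and tracker cells, Poisson shot noise on signal and Gaussian read
noise (SD 10) everywhere, rounded to 16-bit. Because a 25 µm optical section
integrates its whole slab, a blob contributes its full axial weight to the
section containing it.

**Default calibration.** 5 µm/pixel in xy (plausible for a 4× objective
with camera binning; the platform does not publish its pixel size, so this
is a required calibration input with a package default), 25 µm z-step, a
2000 × 2000 µm field and 24 sections (600 µm of gel). A well is then
400 × 400 × 24 voxels — small enough that a full 384-well screen simulates
and analyzes on a laptop, while nuclei stay ~2 px wide and resolvable.

**What the simulator does not emulate** — and hence what green tests do
*not* establish about real data: spherical geometry only (no irregular or
fused-at-seeding clusters), no stroma/fibroblast channel, no
photorealistic PSF or depth-dependent attenuation, no staining gradients,
no cytokines. Recovery results on synthetic wells bound the pipeline's
algorithmic error, not its accuracy on real microscopy.

## Numerical choices and degenerate inputs

* Thresholds "at least" are inclusive (≥) throughout.
* Otsu runs on a 512-bin histogram; intensities beyond 1e6 voxels are
  strided-subsampled (the histogram shape is what matters). Background
  statistics likewise use a deterministic strided subsample.
* A nucleus on a labeled voxel belongs to that component; on a background
  voxel it is a single cell. Plateau ties in maxima detection break by
  linear index.
* Empty wells: an all-background image yields an empty labeling (not an
  error); a blank well measures 0 objects / 0 volume and fails image QC as
  empty.
* A failed stage marks the well `analysis_failed` instead of aborting the
  plate; excluded wells drop out of normalization and aggregation.
* Seeds: one master seed; per-well seeds derive from a polynomial hash of
  (master seed, well id), so plates are reproducible and wells independent.
  All outputs are pure functions of (parameters, seed); identical runs give
  byte-identical CSVs.

## Problem sizes used by the checks

The test suite exercises most mechanics on reduced wells (800 µm field,
10–25 tumoroids) and reserves full default-resolution wells for the
recovery and operating-range checks: a 16-well EVPT screen, two
reconstituted quadruplicate groups, one low-noise well per recovery
property, effect recovery at n = 8 replicates, and 1000 null ANOVA
simulations. The acceptance script reproduces the operating
characteristics at plate scale: two full 260-assay-well EVPT plates for the
exclusion fraction, twenty reconstituted quadruplicate control groups (80
wells) for the replicate CV, and 100 generator wells for the seeding
ranges. These sizes are the package's chosen benchmark configuration; all
are pure functions of the supplied seed.

## Known limitations

* No watershed splitting: touching objects merge (by design, documented).
* Dense nuclei inside large tumoroids merge under the 10 µm separation
  rule, so absolute in-tumoroid nucleus counts are lower bounds; the ≥ 2
  nuclei classification rule and all count readouts are unaffected.
* Small objects near the 50 µm seeding floor span only ~2 optical sections;
  their individual volumes carry digitization error (the per-object 15%
  recovery bound holds for the 95th percentile of matched objects, and
  totals recover to well under 1%).
* The edge-effect and image-QC methods are this package's constructions,
  exposed in configuration, and should be re-tuned for instruments with
  different noise regimes.
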