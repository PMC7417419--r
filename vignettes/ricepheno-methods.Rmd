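---
title: "Methods: drought trait extraction and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought trait extraction and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricepheno)
```

# Scope and model

`ricepheno` quantifies drought responses of rice shoots from four imaging
modalities plus gravimetric pot weighing. The pipeline is a chain of
deterministic operators: RGB segmentation → mask-based shape and color
traits → affine mask transfer into the NIR/IR/fluorescence frame →
modality means → water-budget arithmetic → cohort statistics. This
vignette records the model behind each operator, the tunable parameters,
the numerical conventions, and what the built-in synthetic validation
does and does not demonstrate.

# Segmentation

A pixel is vegetation if its HSV hue lies in `seg_hue_window` (default
20–180°) with saturation ≥ 0.25 and value ≥ 0.10, **or** its excess-green
index 2G − R − B exceeds 0.10. The hue window spans yellow (~60°) through
green (~120°) foliage while excluding the grey pot/background (low
saturation) and soil (hue < 20°). The union of the two rules is
deliberately permissive: drought work must keep *yellowing* tissue in the
mask, and a pure greenness rule would progressively amputate the stressed
canopy, biasing every downstream trait.

The rule image is regularized by a 3×3 (diamond) morphological opening and
closing, and 8-connected components below `min_component_px` (default 50)
are dropped. 8-connectivity keeps thin diagonal leaf segments — common in
side-view rice imagery — in one piece. Raising `min_component_px` can only
shrink the mask (tested as a monotonicity property). Segmentation has no
random element; the same image and config always give the same mask.

The exact foreground rule used by commercial phenotyping software is
proprietary, so no published rule can be reproduced verbatim; instead the
rule here is validated objectively against the synthetic ground truth,
requiring Jaccard overlap ≥ 0.95 across the whole stress grid.

# Shape and color traits

All coordinates are 1-based (row, col) with the row index growing
downward, so drooping canopies *increase* center of mass Y. Conventions
worth recording:

* **Convex hull over pixel corners.** The hull is computed by monotone
  chain over the four corner points of every foreground pixel, not the
  pixel centers. This makes solid convex masks attain compactness exactly
  1 and guarantees hull area ≥ pixel count; center-based hulls produce
  compactness > 1 artifacts on small masks. Correctness is checked
  against an independent O(n³) brute-force hull (every directed point
  pair is a hull edge iff all other points lie to its left) to 1e-9 on
  hundreds of random masks.
* **Compactness** (area / hull area) is the name used in shoot
  phenotyping; it equals what the imaging literature calls solidity.
* **Eccentricity** comes from the moment-equivalent ellipse:
  √(1 − λ₂/λ₁) of the coordinate covariance eigenvalues. The definition
  is fixed only by its endpoints (0 for a circle, 1 for a line); the
  moment form satisfies both (rasterized disc < 0.1, one-pixel-wide line
  ≥ 0.999) and is standard in region-property toolkits. Single-pixel and
  isotropic masks return 0.
* **Perimeter** is the marching-squares contour at level 0.5 between
  pixel centers, holes filled first so only outer boundaries count.
  Contour conventions differ between toolkits by O(1) factors on corner
  treatment, so the convention is frozen by a hand-traceable reference:
  an n×n square measures 4(n−1) + 2√2 and a single pixel 2√2.
* **Extent Y** is read as the axis-aligned bounding-box height. Whether
  the upstream software's "least vertical oriented rectangle" is rotated
  is not documented anywhere; axis-aligned is adopted and recorded here
  as an interpretation.
* **Hue axis.** Plant color uses hue in *degrees truncated at 180*
  (181 bins). Foliage hues never exceed ~180°; rare purples collapse into
  the top bin. Yellow foliage (~60°) falls in the near-yellow stress
  region 0–72 and green foliage (~120°) in the near-green region 73–180,
  with bin 72 inclusive to yellow. The plausible alternative — a
  half-degree axis (hue°/2) — is rejected because it would map green
  (120° → 60) *inside* the yellow window, contradicting the
  stressed/healthy semantics of the two regions. The boundary is
  configurable (`hue_yellow`, `hue_green`) but must partition 0–180
  exactly.

# Registration and modality metrics

The RGB and NIR cameras differ in resolution and position. A 6-dof affine
`nir = A·rgb + b` is fitted by ordinary least squares on control-point
correspondences (≥ 3 non-collinear pairs; 130 points by default, matching
standard rig calibrations). An affine is the smallest class containing
the scale + translation of a two-camera rig while remaining exactly
testable: synthetic correspondences are recovered to machine precision,
and noisy points yield an RMS residual equal to the noise level. The mask
is transferred by nearest-neighbor sampling through the inverse
transform, which preserves binarity; NIR-frame area is reported
separately from RGB-frame area.

* **NIR water index**: 1 / mean reflectance over the mask at the 1450 nm
  water-absorption band. Water absorbs here, so hydrated tissue records
  *low* raw intensity; the reciprocal makes the index increase with water
  content. Absolute sensor calibration is rig-specific, so the index's
  scale is declared arbitrary: orderings and ratios are the contract, and
  homogeneity (index of c·raster = index/c) is tested.
* **Plant temperature**: arithmetic mean °C over the mask. Mean rather
  than median is adopted; with near-uniform canopy temperatures the two
  are close, and the mean matches how rig software reports per-plant
  temperature.
* **Fluorescence**: the fluorescence area is the set of pixels with
  Fm above `fluor_area_frac · max(Fm)` (default 0.05, a free parameter —
  no published threshold exists). Fv = Fm − F0 and the ratios are means
  over that area. Pixels with Fm < F0 are physically impossible (a
  saturating pulse can only raise fluorescence) and are excluded and
  counted; pixels with Fm = F0 are *kept*, since zero variable
  fluorescence is a valid fully-quenched reading (Fv/Fm = 0).

# Water budget

Daily loss rates use the day-0 weight as the 100% base:
rate(d) = 100·(W(d−1) − W(d))/W(0), with weights sampled at a fixed daily
clock time (11:00 by default, the usual mid-morning soil-moisture reading;
configurable). PWLR subtracts the *pooled* empty-pot rate — pairing
planted to individual empty pots is not supported because reference pots
are typically fewer and pooled in practice. Negative PWLR late in severe
drought (a desiccated plant transpires less than bare soil evaporates) is
reported with a warning, never clipped: the sign inversion is a real,
interpretable signal. Series containing irrigation events are refused by
the rate calculation with an instruction to correct for refills first,
rather than silently producing negative "losses". Conservation (daily
losses in grams telescoping to the total weight drop) is an exact
identity and tested as such.

WUE = (dry-mass gain)/(total irrigated water) may be ≤ 0 when mass is
lost; only a nonpositive irrigation total is an error. Group comparisons
use percent difference 100·(a − b)/a with the larger-magnitude mean as
reference `a`, and fold change a/b — the forms used in cohort reporting.

# The synthetic generator

The generator exists so every stage above is testable with no instrument
data. It emulates the *statistical structure* the pipeline assumes, not
photorealism:

* **Geometry.** Leaves are tapered quadratic curves fanning from a stem
  base. Droop rotates the distal half of each leaf toward 115° from
  vertical: tips fall below horizontal (raising center of mass Y) and
  reach farther laterally than the erect fan (widening extent X), the two
  signatures of wilting. Stress additionally *rolls* the leaves,
  shortening the rendered length by up to 35% at full stress — rice leaves
  roll under drought, and this reproduces the several-fold projected-area
  collapse that severe drought produces in real cohorts. Within-plant
  render jitter (leaf length ±3%, angle ±1.5°) is kept small so replicate
  renders of one spec agree in area to within 10%.
* **Color.** Per-pixel hue is a yellow/green mixture (58° ± 6 / 122° ± 8)
  whose yellow weight rises linearly from 0.02 to 0.60 with stress, so
  the measured near-yellow fraction is monotone in stress and < 0.05 for
  an unstressed plant.
* **NIR.** The reciprocal water index is linear in tissue water content
  with endpoints 7.1 (hydrated) and 2.5 (desiccated) — the index range
  NIR phenotyping rigs report for rice shoots; stored reflectance is its
  reciprocal. Linearity on the index scale (the scale practitioners
  compare as ratios) keeps the pooled cohort's area–NIR relation close to
  linear, mirroring the high Pearson correlation seen in real drought
  cohorts.
* **IR.** Plant pixels sit at `base_temperature_c` (default 24.7 °C, a
  typical pre-drought canopy reading) plus `ir_k_c`·stress with
  `ir_k_c` = 3 °C at full stress — comfortably containing the ~1 °C
  genotype separation real cohorts show late in drought — against a 26 °C
  background.
* **Fluorescence.** F0 is constant (0.15) on the plant; Fm = F0/(1 − y)
  with yield y falling linearly from 0.80 (healthy Fv/Fm) to 0.50 at full
  stress, so Fm ≥ F0 holds pixelwise by construction and measured Fv/Fm
  declines monotonically.
* **Frames.** NIR/IR/fluorescence share one frame related to RGB by a
  ground-truth affine (×0.25 downscale plus integer translation),
  emulating the resolution mismatch of real rigs without replicating
  sensor sizes; the truth transform is stored for registration tests.
* **Weighing.** Weight decays by soil evaporation plus
  leaf-area-proportional transpiration on the percent-of-initial basis
  the water budget uses, with 0.5 g observation noise; deviation mode
  refills to the 800 g target at a 5% recorded deficit (trigger 760 g)
  and logs each event. Noise magnitudes are free parameters: published
  cohort tables report only means ± sd, which do not constrain
  pixel/balance noise, so defaults (RGB sd 2/255, balance sd 0.5 g) are
  surfaced in `render_options()` and the simulator arguments.
* **Cohorts.** Tolerant and susceptible groups differ in stress ramp
  slope (0.05 vs 0.13 per day, ±8% per-plant jitter) over an 8-day
  drought, and daily leaf elongation is proportional to 1 − stress, so
  growth stalls as drought deepens — the qualitative growth-rate
  signature of susceptible material. Every stochastic operation takes an
  explicit seed and restores the session RNG; identical seeds give
  byte-identical manifests.

**What passing the synthetic suite does not show.** The generator has a
uniform dark background, no pot, no specular leaves, no occlusion by
neighbors, no illumination drift, and exact (not feature-matched) control
points. Segmentation accuracy and registration overlap on real imagery
will be lower and must be re-validated per rig; the synthetic results
validate the *operators* (definitions, invariances, recoveries), not any
particular camera setup.

# Numerical choices and degenerate inputs

* 1-based (row, col) indexing throughout, the native R matrix convention.
* Empty masks are errors everywhere ("no plant detected" carries the
  image key); one-pixel masks are valid (eccentricity 0, hull area 1,
  perimeter 2√2).
* Float rasters persist as 32-bit TIFF confined to [0,1]; physical units
  ride on an explicit `scale` argument (°C uses scale 100), preserving
  ~1e-5 °C round-trip precision. Readers reject malformed input rather
  than coerce.
* Constant traits make Pearson correlations undefined: those cells are
  `NA` and flagged, never silently 0. Correlations use complete cases
  only; dropped rows are counted.
* Weighing timestamps must be strictly increasing; duplicate timestamps
  are rejected with the offending rows listed.

# Validation problem sizes

The shipped suite exercises: 200 random masks (≤ 20×20) against the
brute-force hull oracle; 130-point registration fits (exact and at 0.5 px
noise); 20 replicate planted/empty weighing pairs for transpiration
recovery at 0.5 g noise; a 5-point stress grid {0, 0.25, 0.5, 0.75, 1}
for every monotonicity hook; and an end-to-end 6-plant × 8-day rendered
cohort for the pooled trait-correlation structure. These sizes were
chosen as the smallest that make the checks statistically meaningful;
all are re-generated in code at test time.

# Known limitations

* The three side views (0°, 120°, 240°) are recorded per row but not
  fused; no multi-view averaging policy is imposed.
* No radiometric IR calibration or emissivity correction; temperatures
  are taken as already-calibrated °C rasters.
* Control points are supplied, not discovered; automatic feature
  matching is out of scope.
* The NIR index's absolute scale is arbitrary without sensor
  calibration; compare indices only within one rig.
* Pot-weight drift from soil compaction is not modeled or corrected.
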