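---
title: "Mapping crop water stress from low-cost infrared scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crop water stress from low-cost infrared scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwsimap)
```

## The measurement problem

A water-stressed plant closes its stomata, transpires less, and warms up
relative to the air around it.  The Crop Water Stress Index (CWSI) turns
this into a 0-1 score by normalizing the leaf-air temperature difference
`dT = T_L - T_A` between two physical limits:

* the **lower limit** `(T_L - T_A)_LL` — how cool a fully transpiring leaf
  can run under the current vapor pressure deficit (VPD), and
* the **upper limit** `(T_L - T_A)_UL` — how warm a non-transpiring leaf
  gets when evaporative cooling stops.

`CWSI = (dT - LL) / (UL - LL)`, so 0 means "no water restriction" and 1
means "no transpiration".  Thermal cameras make this easy but expensive;
`cwsimap` implements the low-cost alternative: a single point infrared
thermometer scanned over the canopy on a gantry, fused with an RGB image
that tells us *which* readings are actually plant.

The chain has five stages, each with its own module:

1. **Scene / bench** (`generate_canopy_scene()`, `simulate_ir_scan()`,
   `generate_environment_series()`, `simulate_soil_moisture()`) — a fully
   synthetic test bench with exact ground truth.
2. **Segmentation** (`excess_green()`, `segment_exg()`,
   `reference_labeling()`, `segmentation_metrics()`) — plant/soil masks
   from RGB and their quality metrics.
3. **Thermal fusion** (`assemble_grid()`, `build_ltm()`,
   `validate_against_reference()`) — the scanned object-temperature grid
   crossed with the mask into a Leaf Temperature Map (LTM).
4. **Baseline** (`vpd()`, `fit_nwsb()`, `lower_limit()`, `upper_limit()`)
   — the non-water-stressed baseline (NWSB) regression
   `dT = a + b * VPD` and the CWSI limits it implies.
5. **Stress mapping and monitoring** (`stress_map()`,
   `treatment_summary()`, `ewma_chart()`, `joint_cycle_report()`) —
   per-pixel CWSI, treatment summaries, and EWMA control charts over the
   crop cycle.

## The synthetic bench: what it emulates, and what it does not

No field data accompany this problem, so the package ships a generator
whose defaults are the study conditions of the physical setup it emulates:
an indoor 0.75 m x 1.50 m soil bench, rows 0.20 m apart, plants 0.05 m
apart within a row, three irrigation treatments occupying equal thirds of
the bench, and a scanning infrared thermometer held 50 mm above the canopy
with a conical field of view, read on a 20 mm grid at noon each day.

Choices the physical description leaves open, fixed here once:

* **Leaf geometry.** Leaves are overlapping ellipses; the default
  110 x 40 mm leaves, 12 per plant, give ~80% canopy cover — a
  late-cycle, nearly closed salad-green canopy.  Cover matters: a 20 mm
  thermal cell that straddles warm soil biases fused leaf temperatures
  upward, and the bias grows as cover falls (see *Known limitations*).
* **Colors.** Plant and soil are Gaussian-perturbed green and brown.  Most
  color noise is a brightness term shared across channels, as illumination
  dominates natural variation; the excess-green index is insensitive to it
  by construction (chromaticity normalization).
* **Temperature field.** Soil runs a configurable `soil_offset` (+3 deg C)
  above ambient.  Leaves follow the baseline model
  `T_A + a + b * VPD` plus a per-treatment additive offset.  The default
  offsets (0, 0.7, 1.0 deg C) were sized so the ideal (mixing-free)
  CWSI contrast between treatments matches the spread reported for
  threshold-irrigated benches of this kind.
* **Sensor.** The default collimated half-angle of 12 degrees gives a
  ~10.6 mm footprint radius at 50 mm height, matching the 20 mm scan cell;
  45 degrees models the uncollimated sensor.  Read noise of 0.25 deg C
  puts ~95% of readings within a +/-0.5 deg C instrument precision.
  Emissivity (0.98 for leaves) is carried as metadata only — no radiance
  model stands behind it.
* **Moisture and irrigation.** Each treatment's volumetric water content
  (fraction of field capacity, FC) dries down linearly (default
  0.04 FC/day) and is recharged by a fixed 0.12 FC whenever a 20-minute
  reading crosses its threshold (0.85 / 0.75 / 0.55 FC).  Jitter is sensor
  read noise on the reading — not on the water balance, which would be a
  random walk that swamps the drydown.  Traces start at their own
  post-irrigation levels, i.e. with the treatments already in regime when
  monitoring begins.
* **Stress coupling.** In cycle simulations the leaf offset grows with
  moisture deficit as `offset = stress_gain * (1 - VWC)`.  The default
  gain of 3 deg C per unit deficit reproduces the reported late-cycle
  situation: a ~0.38 CWSI spread between the wettest and driest treatment
  across a VWC gap of ~0.32 FC under a ~2.6 deg C normalization window.

What the generator does **not** emulate: plant growth over the cycle (the
canopy is geometrically frozen; only its thermal state evolves), wind, dew
and radiative load of an open-air environment, specular soil reflections,
and sensor drift.  Passing tests on this bench therefore demonstrate the
*pipeline's* correctness and sensitivity under controlled contrast, not
field robustness.

## Segmentation

`excess_green()` computes `ExG = 2g - r - b` on chromaticity-normalized
channels; vegetation scores high, soil near zero, and the pure-black pixel
is mapped to the achromatic value 0.  The binarization threshold is not
part of the index; by default `segment_exg()` picks it by Otsu's criterion
on a 256-bin histogram over the observed ExG range (ties across an empty
histogram gap resolve to the gap midpoint), with a fixed-threshold
override.  No smoothing or morphology is applied before or after
thresholding.

The manual-reference procedure (`reference_labeling()`) reproduces how
ground-truth masks are made by hand: sample ten plant pixels, and accept a
pixel when *all three* channel values lie within one standard deviation of
the sampled means (the conjunction is our reading of the procedure; the
source is silent on channel combination).  Note its intrinsic ceiling:
for a roughly Gaussian color population the +/-1 sd band contains only
~60-70% of the class, so whole-image agreement with the truth is high
exactly when the sampled class is a minority of the image.

Metrics follow the standard confusion-matrix definitions with the edge
conventions precision = sensitivity = 0 when their denominators vanish and
F-score = 0 whenever there are no true positives, honoring the anchor
"absence of true positives scores 0, perfection scores 1".

## Thermal fusion and its numerical conventions

Rasters are row-major matrices, origin top-left, and scan cell `(i, j)`
(0-based) centers at `((i + 0.5) cell, (j + 0.5) cell)` mm from the grid
origin.  The thermal raster is resized bilinearly; the mask by nearest
neighbor, which keeps it strictly binary.  Both use corner-aligned
coordinate mapping (output corners coincide with input corners), so
constants are preserved and bilinear output never exceeds the source
extrema.  Off-plant pixels of the fused map are `NA`, never 0 — zero
degrees is a legal temperature, and multiply-by-zero fusion would conflate
the two.

One practical caveat surfaced by the synthetic bench: the resize maps the
*grid raster* onto the *image frame*, so it is only georeferenced if the
scan grid covers (nearly) the same extent as the image.  The pipeline
defaults therefore scan 73 x 36 cells over the full bench (1460 x 720 mm
of 1500 x 750 mm) rather than the bare 61 x 22 figure-map default of
`sensor_spec()`, keeping registration within one cell.

Validation against a reference raster (in the field, a thermal camera)
reports the per-pixel *relative* error `(S - C)/C`, its mean (the general
mean error) and standard error, and alongside them the plain mean
temperature difference in deg C, since reported instrument errors are
usually quoted on that scale.  Zero-temperature reference pixels are
excluded with a logged count rather than propagating an infinity.

## Baseline and limits

`fit_nwsb()` is ordinary least squares of `dT` on VPD with an intercept,
plus the residual diagnostics a regression-validation habit expects: the
residual mean (identically zero), the slope of residuals on fitted values
(a bias check), and a Breusch-Pagan variance-homogeneity test.  A single
pooled regression over the cycle is the default — matching a workflow that
scans once per day — with time-of-day stratification left to the caller
simply by subsetting the observations before fitting.

The lower CWSI limit evaluates the baseline at the ambient VPD of the
scan.  The upper limit uses the potential-VPD construction: extrapolate to
the vapor-pressure gradient `es(T_A) - es(T_A + a)` that would remain if
the air at ambient temperature were saturated.  With `a > 0`, `b < 0` this
gradient is negative and the upper limit exceeds the lower one at every
VPD, which guarantees a positive CWSI denominator.  The exact formula
behind the cited construction is not reproduced in our source; this
reading is isolated in `upper_limit()` so it can be swapped without
touching anything else.

A note on the index formula itself: the typeset form of the CWSI in our
source places `UL - dT` in the denominator, but its own anchor statements
(0 at the lower limit, 1 at the upper) hold only for the canonical
denominator `UL - LL`.  The canonical form is the default;
`cwsi_nwsb(denominator = "literal")` exposes the typeset variant for
comparison.

Out-of-range values are real — they occur whenever the normalization
window is displaced from the actual leaf-temperature range — and are
clipped to [0, 1] after map construction, with the below/above counts
retained on the map object.

## Monitoring

Daily per-treatment CWSI means and normalized soil moisture are charted
with an exponentially weighted moving average,
`z_t = lambda x_t + (1 - lambda) z_{t-1}`, with variance-adjusted control
limits that widen toward `L sigma sqrt(lambda / (2 - lambda))`.  The
smoothing weight and limit width are not dictated by the problem; the
defaults `lambda = 0.2`, `L = 3` follow standard control-chart practice,
with the process center and sigma estimated from the series unless
supplied.  A process is *stable* exactly when no smoothed point leaves the
limits.  Daily means (not all pixels) are charted: one scan per day is the
acquisition cadence, and per-pixel series would mix canopy geometry into
the process signal.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run entirely on generated data at
sizes chosen to exercise every stage within seconds: 64 x 64 px
mini-benches for oracle comparisons (a brute-force per-pixel footprint
enumeration must match the scan simulator to 1e-9 deg C), a 240 x 120 px
quarter bench with a 28 x 14 scan for the hundred seeded end-to-end
ordering runs, the full 600 x 300 px bench with a 73 x 36 scan and the
1280 x 620 fused map for the headline quantities, 30-day 10-minute series
(4320 records) for baseline recovery, and 30-day cycles for the EWMA
verdicts.

## Known limitations

* **Mixed pixels.** With 20 mm cells and +3 deg C soil, fused leaf
  temperatures carry a cover-dependent warm bias (about +0.15 deg C at
  80% cover on the default bench, reported by the acceptance script as
  `ltm_mean_difference_c`).  Treatment *ordering* is robust to it;
  absolute CWSI levels are not, which mirrors the field experience that
  empirical wet/dry references give a narrower, better-anchored index than
  a displaced baseline window.
* **The +/-1 sd reference band** caps the sensitivity of the manual
  labeling procedure near 70% on Gaussian-colored canopies regardless of
  sample count.
* **No radiometry.** Emissivity never enters the simulated signal chain.
* **Frozen canopy.** Cycle simulations vary thermal state, not plant
  size, so segmentation difficulty does not evolve over the cycle as it
  would across a real growth period.
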