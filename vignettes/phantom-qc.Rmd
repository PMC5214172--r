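---
title: "Monitoring PET/CT calibration bias with sealed phantoms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring PET/CT calibration bias with sealed phantoms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcalqc)
```

## The measurement model

A PET scanner reports activity concentration; clinical practice divides it
by injected activity per body weight to form the standardized uptake value,
SUV = A/(I/W) in g/mL. Two instruments enter that number: the scanner
(through its global activity calibration factor, ACF, recalibrated
quarterly at most sites) and the dose calibrator that assays the injection.
`xcalqc` monitors both against sealed Ge-68/Ga-68 sources whose activity is
traceable to a national standard:

* the scanner phantom yields `R_P = A_measured / A_known`, with `A_known`
  the certificate concentration decayed to the scan time;
* the dose-calibrator source yields `R_D = reading / expected`, with the
  expected reading equal to the decayed certificate activity times the
  manufacturer's Ge-68-to-F-18 response factor;
* the SUV bias is `b = R_P / R_D - 1`.

Because `b` is a ratio of ratios, any scale common to both instruments
cancels. The package's job is to compute these three quantities robustly
and repeatedly, so that their drift — not their absolute values — can be
watched.

### Decay handling

All decay corrections use `2^(-t / T_half)`, multiplicative over
concatenated intervals, with negative `t` permitted for back-correction.
Half-lives are explicit, unit-carrying configuration
(`decay_spec()`); the defaults are 270.95 days for Ge-68 (the parent
nuclide governs the sealed source in secular equilibrium; the Ga-68
daughter chain is deliberately not modelled) and 109.77 minutes for F-18.
Timestamps are timezone-aware `POSIXct` and every duration is computed in
seconds: site protocols synchronise clocks to about a minute, so sub-minute
arithmetic precision is ample, but timezone ambiguity would not be.

The Ge-68 to F-18 **response factor has no default** in any computation
that produces `R_D`. It is a property of the dose-calibrator model and
source geometry published on the source datasheet, and a silently assumed
value would bias every record; the example configurations use an
illustrative 0.82, clearly marked as such.

## Automated ROI extraction

The phantom analysis must run with no user intervention, so localisation
cannot rely on a seed point:

1. robust maximum = 99.9th percentile of voxel values (a percentile rather
   than the max so isolated hot voxels cannot steer the threshold);
2. threshold at 50 % of it;
3. largest 26-connected component above threshold, rejected if smaller
   than 5 mL (a 45-mm active cylinder occupies ~70 mL; noise blobs are
   orders of magnitude smaller);
4. intensity-weighted centroid of the component, in physical space.

All four knobs (`robust_percentile`, `threshold_fraction`,
`min_component_ml`, and the CT HU window below) are exposed as arguments
and config keys. The same machinery locates the phantom in CT after
windowing to 0–300 HU, where the epoxy/acrylic insert (~+150 HU) stands
against water (~0 HU, which carries no weight after windowing) — that is
what powers the PET/CT alignment check, with a default 3-mm flag
tolerance.

The ROI is a **cubic bounding box of whole voxels**: along each axis
`n = floor(box_mm / spacing)` voxels, chosen as the contiguous run whose
centres lie nearest the detected centre, with exact ties resolved to the
lower index for determinism. The cube-side interpretation of the box is
what reproduces the published 27/100/294 voxel counts for 10/15/20-mm
boxes on a 2.7 × 2.7 × 3.3 mm grid, and 2 × 2 × 4 voxels for the 15-mm box
on a 5.5 × 5.5 × 3.3 mm grid. The default 15-mm box keeps the ROI at least
~16 mm away from the active-region edge, several PSF widths, so the mean
is insensitive to partial-volume losses at the boundary.

### Two standard-deviation conventions

Within an ROI the statistic describes the enclosed voxel set itself, so
`roi_statistics()` uses the population SD (divide by N) and reports
`u = 100·sd/mean` as the spatial-uniformity metric. Across repeated
measurements the spread estimates an underlying variability, so
`cov_percent()` uses the sample SD (divide by n−1). Neither choice is
forced by the mathematics; both are fixed and documented here so COV
values are reproducible. Percentages compared against printed figures are
rounded half away from zero at the printed precision
(`round_half_away()`).

## The simulator

`phantom_scene()` emulates the physical setup: a 45 × 45 mm active
cylinder at a nominal 250 kBq/mL, mounted 70 mm below the axis of a 20-cm
water flood cylinder, on one of two bundled grids (5.5 × 5.5 × 3.3 mm or
2.7 × 2.7 × 3.3 mm voxels). Rendering choices:

* **Partial volume.** Boundary voxels get analytic in-cylinder fractions
  from 2 × 2 × 2 subsampling. ROIs stay well inside the plateau, so finer
  subdivision changes nothing the analysis sees; interior voxels are
  painted exactly.
* **PSF.** Reconstruction smoothing is a separable Gaussian, default
  8 mm FWHM transaxially and 4.6 mm axially, sampled to 4σ and
  normalised to unit sum (total signal preserved to <0.1 % away from grid
  edges).
* **Noise.** Real post-reconstruction noise is spatially correlated and
  object-dependent; no raw-count model is available to emulate it. The
  simulator adds i.i.d. Gaussian noise after smoothing with SD equal to a
  fraction of the plateau value, default 0.5 %, which puts the intra-ROI
  uniformity `u` comfortably under the 2 % acceptance bound while leaving
  the ROI mean stable to ~0.05 %. A scaled-Poisson model (counts at the
  plateau as the knob) is available when mean–variance coupling matters.
  Seeds are mandatory for stochastic models and are recorded in rendered
  series metadata.
* **Mispositioning.** `misposition()` translates the mount and/or rotates
  it about the flood-phantom axis — the phantom slides around the wall,
  which is the only rotation the physical bracket permits. The active
  cylinder is rotationally symmetric about its own axis, so a phantom on
  the flood axis is a fixed point of rotation; that symmetry is itself a
  test.
* **Bias emulation.** A single multiplicative `scale` per render stands in
  for net attenuation/scatter/calibration bias. Reconstruction physics is
  out of scope, deliberately: the analysis chain only ever sees its net
  multiplicative effect on the plateau.

The CT companion assigns nominal HU (+150 epoxy, 0 water, −1000 air) and
is noiseless; it exists to exercise the alignment check, not to model CT.

### What passing simulations do and do not show

The simulator validates the *software chain*: localisation accuracy,
ROI-rule correctness, unit and decay arithmetic, end-to-end linearity
(a noiseless default scene analyses to R = 1.000 ± 0.001, and an injected
global scale s returns R = s). It does not reproduce OSEM noise texture,
scatter/attenuation interplay with the background medium, CT-tube-voltage
effects, count-rate effects or real scanner calibration drift — all of
which affect measured R on hardware. Conclusions about real-scanner bias
magnitudes cannot be drawn from simulation; conclusions about what the
analysis would report for a given underlying bias can.

## Longitudinal and multisite reporting

Records pair one phantom scan with one dose-calibrator assay taken on the
same UTC calendar day (configurable; `force` overrides). Time series are
segmented wherever the recorded ACF changes by more than a relative
tolerance (default 1e−6, i.e. any change), because recalibration steps
move every subsequent R; within-segment and per-site COVs are reported
separately. The stored `b` of every record is recomputed from its stored
`R_P` and `R_D` on load, and a mismatch is a hard error — a hand-edited
CSV cannot silently poison a report.

## Numerical and interface choices

* Internal activity math is canonically kBq/mL, MBq, kg; SUV is
  body-weight only (`SUV = A·W/I` after unit reduction).
* Voxel indices are 0-based in physical formulas (`x = origin + i·spacing`
  at voxel centres), 1-based at the R surface; the conversion lives in one
  place. Geometry is never defaulted — a series without spacing or origin
  refuses to load.
* Series I/O uses NIfTI voxel data with a JSON sidecar for the metadata a
  quantitative analysis needs (units, rescale slope/intercept, acquisition
  and decay-reference timestamps, per-slice axial positions). Slices are
  assembled by position, never file order; gaps inconsistent beyond 1 % of
  the axial spacing are an error.
* `floor(box/spacing)` is computed with a 1e−9 slack so an exactly
  integer ratio cannot fall to the wrong side of floating-point rounding.
* The command-line wrapper exits 0 on success, 1 on analysis failure
  (phantom not found), 2 on configuration errors, and logs provenance
  (seed, certificate ids) to stderr.

## Problem sizes

The bundled grids render 84 × 84 × 46 (fine) or 42 × 42 × 46 (coarse)
voxel volumes; a render plus full analysis takes well under a second, and
the complete test suite — including five translation and five rotation
recoveries and three noisy uniformity checks — runs in a few seconds.
Property-style suites use 50–200 randomized cases per invariant under
fixed seeds.

## Known limitations

* No DICOM reader: series come from the simulator's NIfTI + sidecar
  format. The reading surface (`read_series()`) is format-agnostic by
  contract, so a DICOM backend can be added without touching the
  analysis.
* The sealed-source model carries the certificate's ±2.5 % stated
  uncertainty as metadata; it is not propagated through derived
  quantities.
* Noise is i.i.d. pre- or post-smoothing; spatially correlated
  reconstruction noise is not modelled (see above).
* Well-counter sources, OSEM reconstruction, and CT-based attenuation or
  scatter physics are out of scope.
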