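---
title: "Simulating the partial volume effect for spherical objects in CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the partial volume effect for spherical objects in CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvesim)
```

## The model

`pvesim` simulates how threshold-based CT volumetry measures a perfectly
spherical, homogeneous object embedded in a homogeneous matrix. The model is
purely geometric and works on raw voxel values: it assumes isotropic cubic
voxels, a uniform density per material, no Compton scattering, no
reconstruction-kernel convolution and no image post-processing. Everything is
expressed in voxel-edge units (`k = 1`), so a single result applies to any
field of view and matrix size; `ct_geometry()` converts to millimetres only
at reporting time.

One simulated measurement proceeds in four stages.

**1. Voxel classification.** The sphere of radius `r_norm` sits at a center
offset inside the central voxel `[-1/2, 1/2)^3` of an integer lattice of unit
cubes. Every voxel within `ceiling(r_norm) + 1` voxels of the center (which
bounds the sphere for any offset) is classified from the exact minimum and
maximum distance between the cube and the sphere center:

* *inside* — the farthest corner is closer than `r_norm`;
* *outside* — the closest point of the cube (per-axis clamp
  `max(0, |d| - 1/2)`) is at distance `>= r_norm`;
* *cut* — otherwise: the sphere surface genuinely crosses the cube.

A natural alternative classifies from the eight corner distances (plus the
voxel center). We deliberately use the exact cube distances instead: corner
sampling misses voxels whose intersection is a thin sliver bulging through a
face or edge, and at small radii those slivers are common enough to bias the
cut-voxel count by several percent. The exact rule is also what a dense
brute-force point oracle converges to, which makes the classification
testable against an independent reference (see `tests/testthat/`).

Points and corners exactly at distance `r_norm` count as *outside* (strict
`<` for inside). Ties occur with probability zero under random offsets, but
the tie-break keeps every function deterministic. One visible consequence: a
unit-radius sphere centered exactly on a lattice corner touches its face
neighbours tangentially and therefore overlaps exactly 8 voxels, while any
nearby interior offset yields 16–20 and a voxel-centered sphere 27. The
`offset_sweep()` grid includes such degenerate boundary points by
construction; random-offset simulations never hit them.

**2. Cut-volume estimation.** The sphere–voxel intersection fraction of a
cut voxel is estimated by regular subdivision sampling
(`sampling_scheme()`): `m` evenly spaced points per axis at offsets
`((1:m) - (m+1)/2)/m` from the voxel center, so each of the `m^3` points
represents a `(1/m)^3` sub-cube, and

```
p_cut = (# sample points strictly inside the sphere) / m^3 .
```

The default `m = 5` (125 points at offsets 0, ±1/5, ±2/5) balances accuracy
against cost. `sampling_error_study()` quantifies the per-voxel error of any
scheme against `exact_cut_volume_oracle()`, a dense regular sampling at 101
points per axis (~1.03 million points). We use a sampled oracle rather than
the closed-form sphere–box integral because it is simple, obviously correct,
and its own resolution error is orders of magnitude below the per-voxel
errors being measured. The error metric is the mean absolute difference
between estimate and oracle, expressed as a percentage of the voxel volume;
it decreases monotonically with `m`.

Random cut voxels for the error study are drawn by sampling a radius
uniformly from `r_range`, a center offset uniformly from the central voxel,
and a voxel whose center is nearest to a uniformly random point of the
sphere surface, rejecting until the exact classification says *cut*. This
samples surface voxels approximately uniformly without classifying a full
grid per trial.

**3. Density mixing and threshold attribution.** A cut voxel with object
fraction `p1` has density `HU_tot = p1*HU_I + (1-p1)*HU_O` (`mix_hu()`). It
is attributed to the object when `HU_tot` lies on the object's side of the
segmentation cutoff, boundary included — equivalently when
`p1 >= p_cutoff = (HU_cutoff - HU_O)/(HU_I - HU_O)` (`p_cutoff()`,
`attribute_voxel()`). The fraction form also covers dark objects in bright
matrices, where the HU inequality mirrors. The two clinical presets are

| preset | HU_I | HU_O | cutoff | p_cutoff |
|---|---|---|---|---|
| `lung_nodule` | 0 | −1000 | −500 | 0.5 (symmetric) |
| `kidney_stone` | 1000 | 30 | 130 | 100/970 ≈ 0.103 (asymmetric) |

**4. Monte-Carlo aggregation.** `run_once()` computes, for one position, the
geometric volume `V_m = n_I + sum(p_cut)`, the true volume
`V_r = (4/3)*pi*r_norm^3`, the threshold volume `V_m_CT = n_sphere` (inside
voxels plus attributed cut voxels) and the ratios `P_approx = V_m/V_r` and
`P_sim = V_m_CT/V_r`. `run_simulation()` repeats this over offsets drawn
uniformly from the half-open cube `[-1/2, 1/2)^3` with R's default
Mersenne-Twister stream and reports arithmetic means with standard
deviations. The precision tables are means over 100 positions;
`build_table()` derives one sub-seed per radius from the master seed
(`seed + 1000*r`), so any subset of radii reproduces exactly the
corresponding rows of the full sweep.

## What the simulation does and does not emulate

The Monte-Carlo conditions are the study conditions: 100 random sphere
positions per radius, 125-point cut-volume sampling, the two density presets
above, and the radius sweep `r_norm ∈ {1..10, 20..70 by 10}`
(`default_radii()`). Under these conditions the simulator reproduces the
characteristic findings: volume conservation (`P_approx ≈ 1` at every
radius), the geometric plateau (mean cut fraction rising from ~20% at
`r_norm = 1` toward 50% for large spheres), strong magnification of small
kidney stones and mild shrinkage of small lung nodules.

It does **not** emulate real CT physics: X-ray spectra, Compton scattering,
detector response, reconstruction kernels, image noise, or the Gaussian
spread of densities inside real tissue. In particular the intra-voxel
density is exactly the volume-weighted mean, so a passing test suite says
the *geometry and thresholding logic* is right — it does not certify
agreement with any physical scanner, where edge-enhancing or smoothing
kernels shift surface voxels further. Non-spherical objects and anisotropic
voxels are out of scope.

## Parameters that matter

* `r_norm` (> 0): object radius in voxel edges; the only size parameter.
  Diameter in mm = `2 * r_norm * fov_mm / matrix_size`.
* `points_per_axis` (default 5): cut-volume sampling density. Raising it to
  10 reduces the per-voxel error several-fold at 8× the cost; the Monte-Carlo
  averages are already stable at 5 because errors largely cancel across the
  many cut voxels.
* `repetitions` (default 100): Monte-Carlo positions. SDs are reported so
  users can size tolerances; large radii need fewer repetitions because the
  position effect decays roughly with the surface-to-volume ratio.
* `hu_inside`, `hu_outside`, `hu_cutoff`: the clinical density context; the
  single derived number `p_cutoff` controls the whole bias structure, and its
  distance from 0.5 measures the asymmetry of the threshold within the
  density window.
* `agatston_window(hu_matrix)` inverts the logic: given the surroundings, it
  returns the calcification density `130 + (130 - hu_matrix)` whose volume is
  measured without bias and the symmetric accuracy window around the 130 HU
  cutoff.

## Numerical choices and degenerate inputs

* Strict-inside tie-break everywhere (`<` for inside, `>=` outside), fixed
  once for determinism.
* Half-open voxel cubes and a half-open offset domain `[-1/2, 1/2)` keep the
  lattice partition exact.
* A sphere smaller than a voxel still cuts the central voxel (its surface is
  interior to the cube); classification handles this because the cube's
  minimum distance is 0 when the center lies inside it.
* `estimate_cut_fraction()` returns multiples of `1/m^3`; a *cut* voxel can
  legitimately estimate 0 or 1 when its sliver is thinner than the sampling
  resolution.
* Vectorized grid classification computes per-axis distance bounds once per
  axis and sums them over the 3-D expansion, making `r_norm = 70`
  (≈ 2.9 million voxels) run in well under a second per position; the
  vectorized path is tested to agree voxel-for-voxel with the scalar
  definition.
* Sub-seeds derived as `seed + round(1000*r)` stay far below `2^31`.

## Problem sizes in the test suite

The unit and property tests run small spheres (`r_norm <= 5`) with 5–100
repetitions, the sampling-error study at 150–300 trials, and one large-sphere
check at `r_norm = 70` with 10 repetitions — sizes at which every reference
quantity we assert is stable to well within its comparison tolerance while
the whole suite completes in seconds. The acceptance script uses the full
study conditions (100 repetitions, 1000 error-study trials).

## Known limitations

* The subdivision estimate is deterministic given the scheme, so its error
  is systematic per voxel (not zero-mean noise); at `m = 5` it can reach a
  few percent of a voxel for unluckily placed slivers. Averages over many
  cut voxels are far more accurate, which is why `P_approx` sits at 1.00.
* `P_sim` for a *single* position is a step function of the offset (voxels
  jump across the cutoff discontinuously); meaningful statements are
  Monte-Carlo means, and small-radius rows carry visible SDs.
* The Agatston analysis covers the density window and density-factor bins
  only; the full area-based score over 2-D slices is not implemented.
* Stones and nodules of clinically mixed composition (e.g. cystine vs
  oxalate densities) are represented only through the single `hu_inside`
  value.
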