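# pvesim — partial volume effect simulation for spheres in CT voxel grids

When a CT voxel straddles two materials, its Hounsfield-unit (HU) value is
the volume-weighted average of both densities. Threshold-based volumetry —
"count every voxel whose density clears a cutoff" — then misestimates the
size of small objects, because surface voxels fall on the wrong side of the
cutoff. This *partial volume effect* (PVE) matters wherever small bright
lesions are sized against a fixed threshold: kidney stones (≈1000 HU in
30 HU parenchyma, segmented at 130 HU) are dramatically magnified, lung
nodules (0 HU in −1000 HU air, segmented at −500 HU) shrink slightly, and
Agatston coronary-calcium scores are inflated for dense plaques.

`pvesim` quantifies this bias with a voxel-exact geometric simulation, for
radiologists, physicists and software developers who need to know how much a
reported stone or nodule volume can be trusted at a given size.

## Model

A sphere of radius `r` lives on an isotropic voxel grid with edge `k`; all
lengths are expressed as the dimensionless ratio `r_norm = r/k`, so one
simulation covers every scanner geometry. For each sphere position:

1. **Classification.** Every voxel in the bounding grid is *inside*,
   *outside*, or *cut* by the sphere surface, decided from the exact minimum
   and maximum distance between the voxel cube and the sphere center.
2. **Cut volume.** Each cut voxel's intersection fraction `p_cut` is
   estimated by subdivision sampling: `m³` evenly spaced points per voxel
   (default `m = 5`, 125 points at offsets {0, ±1/5, ±2/5} of the edge), and
   `p_cut = (points inside)/m³`. The geometric measured volume is
   `V_m = n_I·k³ + Σ p_cut·k³` with `n_I` the fully-inside count, compared
   against the ground truth `V_r = (4/3)π r_norm³`.
3. **HU mixing and thresholding.** A cut voxel's density is
   `HU_tot = p₁·HU_inside + (1 − p₁)·HU_outside`; it is attributed to the
   object when `HU_tot ≥ HU_cutoff`, i.e. when
   `p₁ ≥ p_cutoff = (HU_cutoff − HU_outside)/(HU_inside − HU_outside)`.
   The threshold-measured volume `V_m_CT` counts inside voxels plus
   attributed cut voxels; `P_sim = V_m_CT / V_r` is the volumetry bias
   (1 = unbiased).
4. **Monte-Carlo.** Steps 1–3 repeat over sphere centers drawn uniformly in
   the central voxel (default 100 repetitions); means and SDs are reported.

For kidney stones `p_cutoff = 100/970 ≈ 0.10`: a voxel containing 10% stone
is already counted as stone, so the measured volume of a stone one voxel
in radius is more than double its true volume. For lung nodules `p_cutoff = 0.5` exactly, so the PVE cancels
and only the *geometric effect* remains: small spheres are so strongly
curved that surface voxels hold on average well under 50% object
(20.3% at `r/k = 1`), which shrinks tiny nodules.

## Worked example

```r
library(pvesim)
tab <- build_table("kidney_stone", radii = 1:5, repetitions = 100, seed = 1)
print(tab)
#> PVE scenario table: kidney_stone (5 radii, 100 repetitions)
#>  r/k diameter_mm   n_I   n_T pct_Vr mean_Vcut   V_r   V_m P_sim
#>    1         1.4   0.0  20.3    484      0.21   4.2   4.2  2.29
#>    2         2.7   7.3  76.7    229      0.34  33.5  33.5  1.63
#>    3         4.1  45.8 171.1    151      0.39 113.1 113.1  1.41
#>    4         5.5 141.1 303.2    113      0.42 268.1 268.1  1.30
#>    5         6.8 317.3 472.6     90      0.44 523.6 523.6  1.24
```

Reading the `r/k = 1` row: a stone of diameter 1.4 mm (at the default
350 mm FOV / 512 matrix, voxel edge 0.68 mm) almost never contains a whole
voxel (`n_I ≈ 0`) but cuts ~20 voxels, each holding on average 21% stone.
The geometric volume `V_m` matches the true volume `V_r` (4.2 = 4.2: the
approximation itself is unbiased), yet threshold volumetry reports
`P_sim = 2.29` — 229% of the true volume — because nearly every cut voxel
clears the 130 HU cutoff. By `r/k = 5` (6.8 mm) the bias is still +24%.

The same sphere measured as a lung nodule instead *shrinks*:

```r
run_simulation(simulation_config(1, scenario_preset("lung_nodule"),
                                 repetitions = 100, seed = 1))
#> PVE simulation: r/k = 1, 100 repetitions, scenario 'lung_nodule'
#>   n_I = 0.0, n_T = 21.0, mean V_cut = 0.199, P_approx = 0.999
#>   V_m_CT = 2.9, P_sim = 0.697 (+/- 0.182 sd)
```

And the Agatston accuracy window for calcifications in vessel wall/blood
(50 HU) shows that only ~210 HU calcifications are sized correctly — denser
plaques (density factors 2–4) are systematically oversized:

```r
agatston_window(50)
#> Agatston window for 50 HU matrix: accurate at 210 HU (window 50..210 HU)
```

A command-line wrapper with verbs `run`, `sampling-error`, `agatston`,
`sweep-offsets` and `export-phantom` (NIfTI HU volumes for external viewers)
is installed at `inst/cli/pvesim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pvesim.R", package="pvesim"))')" \
  run --scenario kidney_stone --radii 1-5 --reps 100 --seed 42 --out out/
```

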