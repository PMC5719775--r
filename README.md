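# mrdistort

Grid-phantom mapping and correction of 3D system-related geometric
distortion in MR images.

MR scanners displace structures by several millimetres toward the edges of
the imaging volume — gradient-field nonlinearity plus static-field (B0)
inhomogeneity — which is unacceptable wherever millimetre geometry matters
(the driving application is radiotherapy planning directly on MR images).
`mrdistort` measures the 3D displacement field with a grid-sheet phantom
and rectifies image volumes with it, and ships a complete synthetic
phantom/scanner simulator with analytic ground truth so the whole chain is
testable without scan data.

## Method

A box phantom holds 17 styrene grid sheets (17 × 17 bar crossings each,
15 mm pitch) in mineral oil; a CT scan supplies the true ("world")
coordinates of all 4913 control points, MR scans their distorted
("image") coordinates. The phantom is scanned in three orientations
(transverse, sagittal, coronal — each measures the two in-plane
displacement components) and with both read-gradient polarities (the
B0-induced shift flips sign, so averaging the two positions of each point
cancels it):

* per-point displacement: `δx_i = x_MR − x_CT` (per axis), total
  `δr_i = √(δx² + δy² + δz²)`;
* first-order field estimate per axis: the mean of the two orientations
  that measure it in-plane, e.g. `δx⁰ = (δx_tra + δx_cor)/2`;
* iterative refinement: each axis is re-evaluated by spline interpolation
  of the measured samples at coordinates corrected by the other axes'
  latest estimates — `δxⁿ at (x, y+δyⁿ⁻¹, z+δzⁿ⁻¹)`, then
  `δyⁿ at (x+δxⁿ, y, z+δzⁿ⁻¹)`, then `δzⁿ at (x+δxⁿ, y+δyⁿ, z)` — until
  every per-point change falls below φ = 0.2 mm (converges in ≤ 4
  iterations; a guard falls back to the first-order values if the changes
  grow). This removes the bias the first-order estimate inherits when the
  in-plane components vary through-plane;
* tensor cubic splines interpolate the converged samples into a continuous
  distortion map; volumes are rectified by resampling at `x + δ(x)`;
* validation re-runs the *entire* pipeline on the corrected volumes: the
  measured residual distortion is the method's figure of merit.

Control points are extracted per slice with sub-voxel accuracy: unsharp
masking normalised by the local intensity level (cancels the multiplicative
coil-sensitivity bias), per-slice adaptive thresholding (median plus a
robust noise offset), directional line blurs whose combined response
isolates the grid-line crossings (suppressing air bubbles and streaks),
watershed separation, area and line-support filters, and
intensity-weighted centroids merged across the slices of each sheet.

See `vignettes/distortion-mapping.Rmd` for the full account of the model,
the parameters and the design decisions.

## A worked example

```r
library(mrdistort)

geom  <- phantom_geometry()        # 17 sheets of 17 x 17 points
model <- default_study_model()     # degree-3 field, ~5 mm max, plus B0
study <- simulate_study(geom, model, seed = 7)  # CT + 6 MR volumes

report <- run_study(study)         # extract -> register -> estimate ->
report                             #   correct -> residual-validate
#> <study_report>
#>   CT points: 4913; orientations: transverse, sagittal, coronal
#>   iterations: 2 (converged)
#>   distortion found (iterative):
#>   axis mean_mm sd_mm max_mm    n
#> 1    x   1.727 0.913   3.75 4335
#> 2    y   1.728 0.909   3.63 4335
#> 3    z   0.789 0.761   2.63 4335
#> 4    r   2.781 1.046   5.16 4335
#>   residual after correction (iterative):
#>   axis mean_mm  sd_mm max_mm    n
#> 1    x   0.109 0.0644  0.345 4228
#> 2    y   0.109 0.0671  0.334 4228
#> 3    z   0.126 0.0929  0.364 4228
#> 4    r   0.222 0.0873  0.479 4228
```

The report says: the simulated scanner displaced control points by up to
5.2 mm (mean 2.8 mm) over the 260 × 260 × 240 mm analysis volume; after
estimating the field from the six MR volumes and rectifying them, re-running
the whole measurement on the corrected volumes finds at most 0.48 mm of
residual displacement (mean 0.22 mm) — distortion has been mapped and
corrected to well within the voxel size of the simulated acquisition.
(Correcting with the non-iterative first-order field instead leaves a
larger maximum residual, 0.50 mm — the iteration's through-plane
correction at work.) `tidy()`
and `glance()` give the same tables as tibbles, `autoplot(report$fit)`
draws the per-slice maximum profiles, and `plot_distortion_slice()` maps a
single plane.

Individual stages are ordinary functions over tibbles
(`extract_control_points()`, `average_forward_reverse()`,
`register_ct_to_mr()`, `clean_with_polynomial()`,
`match_correspondences()`, `per_axis_displacement()`,
`first_order_estimate()`, `iterate_field()`, `build_map()`,
`correct_volume()`), so any sub-chain can be run and inspected on its own;
`inst/cli/mrdistort` wraps them as shell subcommands
(`simulate / extract / register / map / correct / run`) over NIfTI and CSV
files.

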