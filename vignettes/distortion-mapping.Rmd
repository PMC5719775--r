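---
title: "Mapping and correcting MR system distortion with a grid phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and correcting MR system distortion with a grid phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mrdistort)
```

## The problem

MR images carry geometric distortion from two scanner-related sources:
nonlinearity of the spatial-encoding gradients and inhomogeneity of the
static field (B0). For applications that need millimetre spatial fidelity —
radiotherapy planning on MR images being the canonical one — the distortion
over the imaging volume must be *measured* and the images *rectified*.

`mrdistort` implements a phantom-based workflow for this. A box phantom
holds a stack of styrene grid sheets in mineral oil; the grid-bar crossings
("control points", 17 sheets of 17 × 17 points by default) sample the
volume on a known lattice. A CT scan of the same phantom, treated as
distortion free, supplies the true (world) coordinates of every control
point — including any manufacturing warp of the sheets, which is why the CT
reference is preferred over the nominal design geometry. The displacement
between each point's MR position and its CT position samples the distortion
field; splines interpolate those samples into continuous maps used to
resample (rectify) image volumes.

Because the grid sheets provide crossings in only one plane, the phantom is
scanned three times, rotated so the grid profile lies in the transverse,
sagittal and coronal planes; each orientation measures the two in-plane
displacement components. Every scan is acquired twice with opposite
read-gradient polarity: the B0-induced shift flips sign with the polarity,
so averaging each point's two positions cancels it and isolates the
gradient-nonlinearity (system) component.

## The measurement model and why iteration is needed

A subtlety drives the method's central algorithm. Each orientation measures
a point's in-plane displacement *in the slice where the point appears* —
and if the field also displaces the point through-plane, that slice is not
at the point's true through-plane coordinate. The in-plane measurement is
therefore the in-plane field evaluated at the *apparent* through-plane
coordinate. A "first-order" estimate that simply averages the two
orientations' in-plane measurements per axis inherits this bias wherever
the in-plane components have through-plane gradients.

The estimator removes the bias by iterating: the x component is
re-evaluated (by spline interpolation of the measured samples) at
`(x, y + dy, z + dz)` using the latest y and z estimates, then y at
`(x + dx, y, z + dz)`, then z at `(x + dx, y + dy, z)`, until every
per-point component change falls below a cutoff `phi` (0.2 mm by default, a
further reduction not improving the residual). Convergence takes at most a
few iterations on smooth fields; a guard returns the first-order values if
the changes ever grow instead of shrink. The converged values solve the
fixed-point equations `dx = dx(x, y + dy, z + dz)` (and cyclically), which
is exactly the displacement needed to rectify images acquired under this
slice-wise measurement; the package exposes the analytic fixed point of a
known model (`fixed_point_displacement()`) as the corresponding oracle.
When the field has no through-plane coupling the fixed point coincides with
the plain field and the iteration terminates after one confirming step.

Two implementation choices matter here and were genuinely open:

* **Sample housing.** During iteration, each orientation's in-plane
  samples are housed at their CT in-plane coordinates but at their
  *apparent* through-plane coordinate (a "sheared" lattice, interpolated by
  per-node natural splines through the regular in-plane lattice). That is
  what makes the shifted lookups above land on the right measurements.
* **Cross-orientation association.** The three acquisitions rotate the
  phantom, so the three CT lattices do *not* coincide (sheet pitch 16.6 mm
  vs in-plane pitch 15 mm). Nearest-site association across lattices would
  alias values by up to ~8 mm of site offset; instead each orientation's
  contribution to the per-axis double estimate is read off a CT-housed
  tensor-spline interpolant evaluated at the common (transverse CT) sites —
  exact at the orientation's own sites, and consistent with the iteration's
  positional lookups.

## The simulator

Every stage is testable without scan data through a built-in simulator with
analytic ground truth:

* **Phantom rasterization** uses exact per-axis partial-volume fractions of
  the axis-aligned bar/sheet geometry (no supersampling needed), so
  detected centroids have sub-voxel ground truth. Bars span the full sheet
  so that edge crossings respond like interior ones. The bar width is not
  part of the published phantom description; 2 mm is used as a realistic
  value for commercial styrene grid sheets.
* **The forward acquisition model** implements the slice-stack measurement
  described above: the through-plane field component selects the slice
  where material appears, and the in-plane components are evaluated at the
  nominal coordinate of that slice. It reduces exactly to the plain warp
  `x -> x + delta(x)` for fields without through-plane gradients. Volumes
  are rendered by fixed-point inversion of the apparent-position map at
  each voxel, evaluating the analytic phantom intensity at the pre-image.
* **Artifacts**: a seeded multiplicative bias field (zero-mean mixture of
  broad Gaussians, default amplitude 30 %), additive Gaussian noise
  (default sigma 5 % of the oil signal), and air bubbles (dark ellipsoids,
  default 10, kept a guard radius of 5 mm away from the apparent control
  points so the ground-truth point count stays exactly 17^3).
* **The default study field** is a degree-3 polynomial with ~5 mm maximum
  total displacement over the control volume and deliberately strong
  through-plane (z) gradients in the in-plane components (a Chebyshev-style
  cubic z profile), plus a quadratic B0 term of ~2 mm at the edges — the
  regime in which the iterative estimator visibly outperforms the
  first-order one. The true scanner field's functional form is unknown;
  this family is a stand-in chosen for smoothness and realistic magnitude.

What the simulator does *not* emulate: MR physics (relaxation, k-space
artifacts, susceptibility boundaries — B0 is modelled purely as a
polarity-signed displacement), sheet warping (irrelevant once CT is the
reference), object-induced distortion, or scanner reconstruction filters.
Passing tests therefore demonstrate the pipeline's correctness under its
stated measurement model, not robustness to every artifact of real scans.

## Control-point detection

Detection runs per slice (the grid profile lies in the slice plane):

1. **Contrast normalisation.** A strongly blurred copy (sigma three times
   the grid pitch, boundary-corrected) estimates the local intensity level;
   the residual divided by that level — sign-flipped for MR so the grid is
   positive — is a relative-contrast image in which a multiplicative bias
   cancels and bar "mass" is uniform across the slice and the volume. The
   classic difference-only unsharp mask is available as `unsharp_mask()`;
   the ratio form is what makes the downstream response levels
   slice-invariant. Slices whose 90th contrast percentile falls below a
   floor (0.25) contain no grid (oil gaps between sheets) and are skipped.
2. **Adaptive threshold.** Per slice, median plus three robust standard
   deviations, with the noise scale estimated from the *negative* residuals
   only (the grid contributes only positive contrast). This keeps the
   threshold just above the slice's own noise floor, preserving
   partial-volume bar pixels — essential because a 2 mm bar straddling two
   voxel columns splits its mass into two half-strength pixels; a threshold
   referenced to bar intensity would delete such bars in a moiré pattern
   across the grid.
3. **Line-intersection masking.** The masked contrast image is blurred with
   a 1D Gaussian along each in-plane axis (sigma one third of the pitch,
   plus a small cross-axis sigma of one bar width). Each directional
   response is normalised by the local grid density (so partial sheet
   coverage in warped regions does not suppress it) and referenced to the
   robust bar-parallel level of the slice (0.7 quantile of on-grid
   responses). Pixels where *both* responses exceed 0.6 of their bar level
   keep the geometric-mean response: the crossings. The geometric mean
   (rather than the sum) prevents a dot from sliding along a strong bar
   when the orthogonal line is locally weak.
4. **Watershed and filters.** Watershed separates touching dots; regions
   outside the expected dot-area window are discarded (frames, streaks,
   clumps); and a *line-support test* rejects compact blobs — at a true
   crossing each directional response stays near its peak along a ±6 mm
   window through the dot (the grid lines are long), whereas an air
   bubble's response collapses beyond its own extent. A 10 mm border margin
   is excluded (blur support is truncated there).
5. **Centroids.** Each coordinate comes from a background-subtracted
   marginal profile of the contrast over a fixed symmetric window
   (±3.2 mm) around the dot's peak: summing the window along one axis
   turns the orthogonal bar into a *constant* baseline (it crosses the
   whole window), so subtracting the marginal's median isolates exactly
   the bar that localises that coordinate, with the partial-volume
   sub-voxel information intact. The symmetric fixed window — rather than
   the thresholded region itself — means a lopsided region (skewed, say,
   by a nearby bubble's blurred response) cannot bias the estimate.
6. **Per-sheet merging.** Per-slice detections are grouped into sheets
   (runs of slices with at least half the maximal per-slice count, split at
   through-plane gaps above 4.5 mm), associated across slices within
   4.5 mm in-plane, and averaged with the per-slice dot mass as weight.
   The through-plane coordinate is then refined from the contrast-mass
   profile in a fixed in-plane window across the sheet's slices — giving a
   sub-voxel apparent through-plane position that is independent of the
   per-slice segmentation.

On the default synthetic phantom at acquisition resolution
(0.9 × 0.9 × 1.0 mm) with 30 % bias, 5 % noise and 10 bubbles, this
recovers all 4913 control points with a maximum centroid error below one
voxel; the acceptance suite verifies exactly that, and the global-threshold
baseline (`threshold_mode = "fixed"`) demonstrably loses points on slices
away from its reference slice under the same bias.

## Registration, cleaning, matching

The registration frame is the scanner isocenter, where distortion is
negligible. The CT-to-MR shift is estimated per orientation: the CT
z-extent midplane is aligned to the MR z = 0 plane, then the residual
translation is the mean CT-minus-MR displacement over control points within
26 mm of the isocenter. (The mean over a symmetric neighbourhood cancels
the linear field term; a single-point estimate would inject its full
detection noise as a rigid bias into every displacement sample.) Rotations
are not modelled — the phantom jig guarantees ~1 mm positional
reproducibility. The rotated orientations reuse the single transverse CT
scan via exact coordinate-axis permutation of the point set.

Artifact points that survive detection (about a handful per volume) are
removed by the per-sheet polynomial cleaning: a degree-3 2D fit maps CT
in-plane coordinates to MR ones per sheet, and MR points farther than 3 mm
from the prediction at their provisionally matched CT site — or matching no
CT site within half a pitch — are dropped. The polynomial is used only for
rejection, never as the field model (the real field is not well described
by a global cubic). Matching is then a greedy distance-sorted one-to-one
assignment within half the grid pitch (7.5 mm), which is unique for fields
below half a pitch. The cleaning tolerance and match radius are
configuration parameters; their defaults bracket the ≤ 6 mm field regime.

## Numerical choices

* Interpolants are tensor-product natural cubic splines (exact at sites);
  scattered fall-back is inverse-distance weighting, used only if the
  sites do not form a lattice. A few missing lattice nodes (undetected or
  cleaned points) are filled by iterative neighbour averaging — within a
  single sheet layer for the apparent-coordinate arrays, so the sheared
  housing stays monotone.
* Extrapolation beyond the sampled volume is linear (natural-spline end
  slope) up to one pitch, then clamps; near-boundary lookups during
  iteration rely on this.
* Correction resamples the input volume at `x + delta(x)` (so the map,
  defined as MR minus CT at CT sites, drives correction without
  inversion), with Catmull-Rom cubic intensity interpolation by default
  and the oil level as out-of-volume fill (a dark fill would masquerade as
  grid structure when the corrected volume is re-analysed). No Jacobian
  intensity modulation is applied. For patient-like volumes not centered
  at the isocenter, the in-plane offset `FOV/2 - header position` relocates
  the map lookup.
* A sample-level outlier screen runs after estimation: a per-site
  component deviating more than 1.5 mm from the median of its six lattice
  neighbours is a measurement artifact (the field cannot vary that fast
  between adjacent control points) and is replaced by that median. It is
  applied identically to the first-order and iterated estimates and in the
  residual re-run, so comparisons between them are unaffected.
* Summary statistics are computed over a 260 x 260 x 240 mm volume of
  interest. The outermost sheets along z lie beyond the other two
  orientations' in-plane lattices, so their cross-orientation lookups rely
  on extrapolation; the sampled field and the maps still cover them, but
  they are excluded from the headline statistics.
* All randomness flows from explicit seeds; identical seeds give
  bit-identical volumes and reports.

## Problem sizes

The packaged tests and the acceptance script run the full pipeline at half
resolution (1.8 × 1.8 × 2 mm volumes, ~3.4 M voxels each, seven volumes
per study) and the detection-accuracy check at full resolution
(0.9 × 0.9 × 1.0 mm, ~27 M voxels) — sizes chosen so a complete study
(simulation, extraction of seven volumes, estimation, correction of six
volumes, and a second full pipeline pass on the corrected volumes for
residual validation) completes in minutes on one CPU. Unit tests use a
3-sheet, 5 × 5-point miniature of the same phantom.

## Known limitations

* The slice-stack measurement model is the package's own account of why
  the first-order estimate is biased; real scanners add sequence-dependent
  effects (eddy currents, concomitant fields) outside its scope.
* Object-induced distortion (susceptibility, chemical shift) is explicitly
  out of scope; the system map combines with any such correction applied
  separately.
* Detection assumes the grid profile lies in the slice plane and that
  distortion stays below half the grid pitch (beyond that, matching is no
  longer unique).
* Residual statistics inherit the detection noise floor (~0.2 mm per
  point at half resolution); residuals below that are not resolvable.

## A worked example

```{r example}
library(mrdistort)

geom <- phantom_geometry()
model <- default_study_model()
study <- simulate_study(geom, model, seed = 1)

report <- run_study(study)
report$fit          # iterations, convergence
tidy(report$fit)    # per-axis mean/sd/max displacement
glance(report$fit)

# residual distortion after correction, per axis
report$residual$stats

# figures
autoplot(report$fit)
plot_distortion_slice(report$map, z_mm = 87)
```
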