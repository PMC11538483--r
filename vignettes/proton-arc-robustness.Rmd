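---
title: "Comparing proton arc and IMPT plans on synthetic 4D thorax phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing proton arc and IMPT plans on synthetic 4D thorax phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and intent

`protarc` is a desk-scale research pipeline for studying how proton arc
therapy (PAT, one gantry revolution with a single energy layer per
direction) compares with 3-beam intensity-modulated proton therapy
(IMPT) on a moving lung target: plan quality against clinical goals,
robustness to setup and range errors, sensitivity to the interplay
between breathing motion and spot-by-spot delivery, normal tissue
complication probability (NTCP), and beam delivery time (BDT).  Real
4D-CT cohorts and commercial treatment planning systems are not
reproducible on a desk, so every input is synthetic and every physics
component is a simplified, documented surrogate.  The pipeline
reproduces the *analysis*, with full control of the ground truth; it
makes no claim of Monte Carlo dosimetric fidelity.

## The synthetic 4D phantom

`build_phantom()` renders a piecewise-constant thorax on a regular grid
(default 64 voxels at 2.5 mm isotropic, echoing a typical dose grid):
an elliptic-cylinder body (relative stopping power 1.0), two ellipsoidal
lungs (0.26), a heart sphere, an esophagus cylinder, a vertebral column
(1.4) enclosing a spinal canal, and a spherical gross tumor volume
(GTV, 1.05) inside the right lung.  Material edges follow an
error-function profile of width `edge_sigma_mm` (default twice the
voxel size) so trilinear interpolation of the density is accurate; ROI
masks are exact indicator functions on the mid-position grid.

Breathing is a rigid craniocaudal translation of the GTV along a 1-cos
trajectory (default 8 mm peak-to-peak over a 4 s period, 10 phases,
uniform time weights), blended into the static lung by a cosine-squared
taper.  The forward motion map is `T_p(y) = y + delta_p * w0(y)`; its
inverse is computed to 1e-10 by fixed-point iteration (a contraction
whenever the amplitude times the taper gradient is below one, which the
constructor enforces by rejecting tumors whose moving region would
leave the lung).  Phase densities are the analytic mid-position density
composed with the exact inverse map, so:

* `dvf_to_midp` (phase grid) and `dvf_from_midp` (MidP grid) are exact,
  which makes dose-accumulation oracles exact;
* the GTV translates rigidly (the taper's inner radius exceeds the GTV
  radius plus half the amplitude);
* the time-weighted mid-position volume reconstructed by warping and
  averaging the phases agrees with the analytic MidP density to within
  interpolation error (tested at 2% of the lung-tissue density
  contrast).

What the phantom does *not* emulate: CT Hounsfield calibration and
noise texture, hysteresis or irregular breathing, baseline drift,
deforming organs at risk.  Passing tests therefore demonstrate
correctness of the pipeline's mechanics, not performance on clinical
images.

## Structures and margins

The clinical target volume (CTV) is the GTV expanded isotropically by
5 mm.  Margin expansion is Minkowski dilation on the voxel lattice: a
voxel joins the expansion iff its center lies within the margin of a
source voxel center (equal to Euclidean distance-transform
thresholding); anisotropic margins dilate by the axis-aligned ellipsoid
with the six directional margins as semi-axes.  One lattice subtlety is
documented here deliberately: dilating twice by margins `a` then `b` is
a *subset* of dilating once by `a + b`, because the intermediate point
must itself be a voxel center — the continuum identity holds only
approximately on a grid, and the tests assert the lattice-true
direction.

The total setup margin (default 8 mm, configurable per direction) is
split in the standard way: 5 mm isotropic is handed to the robust
optimizer as its setup-error magnitude and the remainder becomes a
geometric CTV expansion (`CTVexp`), which carries all robust objective
terms.  Robustness *evaluation* uses the raw CTV with the full margin
as the shift magnitude, mirroring common practice of optimizing on an
expansion but evaluating coverage on the unexpanded target.  Van
Herk-style margin coefficients are inputs, never hard-coded.

## The dose engine

A deliberately simple analytic pencil-beam model, chosen so that setup
shifts, range scaling and density changes perturb dose through actual
physics (water-equivalent path length, WEPL) rather than through
lookup tables:

* depth dose: an entrance plateau (35% of peak) blended into a Gaussian
  peak with an asymmetric sharp distal edge; the nominal range is
  defined at the distal 80% falloff.  The distal width is
  `0.01 R + 0.5 mm`, so the peak sits within a voxel of the nominal
  range on the default grid;
* lateral profile: a Gaussian whose sigma grows linearly with WEPL
  (default 5 mm + 0.03 mm per mm), truncated at 4.5 sigma;
* WEPL: trapezoidal integration of density along the ray at a 1 mm
  marching step, computed per spot ray and interpolated at each
  evaluation point's projection;
* geometry: parallel rays (infinite SAD), gantry rotating about the
  craniocaudal axis;
* scenarios: a positive setup shift moves the patient (rays shift by
  its negative); a range error multiplies the nominal range by
  `1 ± 3%`.

Nuclear halo, RBE weighting, in-air divergence and lateral
heterogeneity scattering are out of scope.  The machine energy table
spans nominal ranges of 10-320 mm in 2 mm steps; the low end stands in
for the range-shifter reach a clinic would use for shallow lung
targets, and, like all beam and timing constants in
`machine_config()`, is a surrogate value, not a vendor measurement.

## Planning and minimax optimization

`place_spots_impt()` covers the CTVexp per beam with energy layers
every 5 mm WEPL (snapped to the machine table) and a rectangular
lateral spot grid at one-sigma spacing.  `place_spots_pat_elsa()` steps
one revolution at 1-2 degree spacing and assigns exactly one energy
layer per direction — the energy whose peak sits at the target's mid
WEPL along that ray, with a bounded energy step between neighbouring
directions; directions whose entry path crosses a configured avoidance
ROI (e.g. the contralateral lung) carry no spots.  This honors the
published contract of early energy-layer-and-spot assignment (one
geometry-driven layer per direction) without attempting to reproduce
any proprietary selection algorithm.

Spot weights are optimized by worst-case minimax: minimize over
nonnegative weights the maximum over scenarios of the robust composite
(quadratic one-sided penalties on CTVexp minimum and maximum dose,
normalized by the squared dose level) plus nominal-scenario OAR terms
(mean/max penalties mirroring the clinical goals).  The max is smoothed
by log-sum-exp with an increasing temperature schedule (default 50,
500 — by the last stage the soft max is within a fraction of a percent
of the hard max for the objective magnitudes that occur here), each
stage solved by bound-constrained L-BFGS-B with analytic gradients on
precomputed per-scenario dose-influence matrices.  ROIs are subsampled
deterministically to at most 1500 voxels per structure for the
objective.  Ties between equally-bad scenarios resolve by scenario
order.  With one scenario the composite reduces exactly to ordinary
optimization; optimality over nested scenario sets is tested against a
brute-force 200 x 200 weight grid on a two-spot problem.

Normalization is a single exact global rescale: dose is linear in the
weights, so setting CTV D50% to the 60 Gy prescription is exact to
machine precision, and the pipeline verifies it by recomputing the DVH.

## Scenario robustness evaluation

`enumerate_scenarios()` builds the setup x range x phase grid: the six
axis-aligned shifts at the configured magnitude plus the nominal case,
range scales `{0.97, 1, 1.03}`, and the chosen phases — 7 x 3 x 4 = 84
scenarios for the standard four-phase setting.  Structures follow the
tumor into each phase through the exact deformation fields (the
phantom's counterpart of contour propagation).  `worst_case_metrics()`
takes the worst value *per metric* across scenarios (minimum for
coverage goals, maximum for sparing goals) — the composite convention
of TPS robustness tables — and judges each clinical goal on the
nominal and/or worst value according to its scope.

One behaviour of the default study conditions is worth flagging.
Evaluation is deliberately harsher than optimization: the optimizer
sees 5 mm shifts on the expanded CTV, while evaluation applies the full
total margin (8 mm by default) to the raw CTV, and the worst scenario
stacks that shift on the breathing excursion.  With this engine's broad
analytic penumbra (lateral sigma 5-7 mm at depth, versus the sharper
penumbra of a clinical Monte Carlo beam model) the stacked ~12 mm
displacement leaves the far target cap in the penumbra tail, so
worst-case D95%/D98% on the default phantom fall well short of the
57 Gy goal while the nominal case is only marginally below it.  This
is a property of the surrogate physics, not of the optimization: the
robust plan still dominates a nominal-only plan in the worst case (a
tested invariant), and sharper beam models would close most of the
gap.  Conclusions about absolute goal compliance should therefore not
be read off this engine.

## Interplay simulation and DVH bands

`simulate_timing()` provides delivery schedules: IMPT beams are
sequential with descending energy layers, spot durations from weight
over MU rate plus switching overheads, and couch-plus-gantry travel
between beams; PAT is one continuous rotation (zero inter-beam travel)
that dwells only when spot delivery or an energy switch is slower than
the rotation.  `distribute_spots_to_phases()` assigns each spot,
treated as instantaneous at its start time, to
`(floor(((t mod T)/T) P) + start) mod P` under uniform phase dwell
times.  `accumulate_4ddd()` doses each phase's spots on that phase's
density and pulls the partial dose back to the mid-position by
evaluating directly at the DVF-mapped point positions — the continuous
form of deform-and-sum accumulation, free of regridding error, and
summed in fixed global spot order so that a motion-free phantom yields
bit-identical accumulated doses for every starting phase (the
zero-amplitude DVH band is exactly zero, not merely small).  Sweeping
all 10 starting phases gives 10 interplay scenarios; the spread
(max - min) of CTV D98% and D1% across them is the DVH band, the
robustness figure of merit.  One treatment fraction is simulated;
multi-fraction averaging is deliberately out of scope.

## NTCP, delivery time and statistics

NTCP models are logistic in a mean organ dose plus optional clinical
covariates: 2-year mortality driven by mean heart dose, grade >= 2
pneumonitis by mean lung dose, grade >= 2 dysphagia by mean esophageal
dose, evaluated on the nominal scenario only.  The shipped coefficients
are editable literature-informed surrogates for a national indication
protocol whose exact parameters are not redistributed here; any
clinical-style use must replace them.

Paired cohorts (e.g. 10-20 phantom geometries planned with both
modalities) are compared metric-by-metric with the Wilcoxon signed-rank
test (exact distribution for n <= 25 without ties), reporting the
median of paired differences; differences with p > 0.05 are reported
as non-significant and no multiple-testing correction is applied,
matching the reporting convention of small planning studies.

## Numerical choices and degenerate inputs

* DVH metrics interpolate the descending-sorted voxel doses at midpoint
  plotting positions `(i - 1/2)/n`, clamped to the extremes, so
  `D100%` is the minimum and `D0%` the maximum dose; `Dycc` queries
  beyond the ROI volume are errors.
* Homogeneity index `(D2% - D98%)/D50%` and Paddick conformity at the
  95% isodose are defaults with the RTOG ratio available; both
  definitions are echoed in the output.
* Empty plans deliver in zero time; rays missing the grid deposit zero
  dose (not an error); non-positive range scales, empty phase lists,
  empty masks, expansions beyond the grid and unknown ROIs are errors.
* The fixed-point inverse of the motion map is iterated to 1e-10;
  geometry is deterministic, and the only randomness (optional density
  noise) is seeded.

## Problem sizes used in tests and the acceptance script

The test suite exercises mechanics on 32 cubed voxel, 5 mm phantoms
with reduced scenario sets (7-21 scenarios, 40 optimizer iterations per
temperature stage), where a full plan-and-evaluate cycle takes seconds;
the acceptance script runs the default 64 cubed, 2.5 mm phantom with
the full 84-scenario minimax optimization.  These sizes are the
package's chosen desk-scale study conditions: large enough for the
dose, margin and interplay behaviour to be resolved, small enough to
iterate on interactively.

## Known limitations

Surrogate Bragg curve and beam model; rigid single-structure motion;
no Monte Carlo transport; no deformable OARs; single-fraction
interplay; NTCP coefficients are placeholders; arc delivery timing is
a kinematic surrogate, not a vendor algorithm.  Conclusions drawn with
this package are about the *methods pipeline*, not about patients.
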