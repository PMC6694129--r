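---
title: "Measuring pennate muscle architecture from tractography and ultrasound: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pennate muscle architecture from tractography and ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleArch)
```

## The problem

Fascicle length (FL), pennation angle (PA) and muscle thickness (t_m)
determine a pennate muscle's excursion and force capacity, and change
with pathology (e.g. post-stroke spasticity). Two *in vivo* measurement
routes are in routine use: 2D B-mode ultrasound, where an operator
digitizes aponeurosis lines and fascicle segments in a single image
plane, and diffusion-tensor MRI tractography, where streamlines along
the principal diffusion direction reconstruct fascicles in 3D. They
disagree in practice — the ultrasound plane may be misaligned with the
fascicle plane, the probe compresses the tissue, and deep muscles image
poorly — so quantifying that disagreement, subject by subject, requires
both pipelines plus a way to place the ultrasound plane inside the MR
volume. This package implements all three components and a synthetic
phantom that makes the whole chain testable against exact ground truth.

## The phantom: what it emulates, and what it does not

`makeUnipennatePhantom()` builds the slab idealization of a unipennate
compartment: the region between two parallel aponeurosis planes, clipped
to a box. The world frame is right-handed millimetres with the line of
action along +y and depth along +z; the deep aponeurosis is the plane of
smaller z. Fascicles are straight lines at the prescribed pennation
angle, so

FL = t_m / sin(PA)

holds analytically and every downstream estimate has an exact oracle.
The tensor field is prolate (λ2 = λ3) with its principal eigenvector
along the fascicle direction and a mean diffusivity of 1.5e-3 mm²/s,
typical of muscle; the single free eigenvalue ratio is solved from the
requested fractional anisotropy (0.35 inside the muscle, within the
tracking window; 0.05 outside, below it, so streamlines terminate at the
muscle boundary). Default voxel size is 2.5 mm isotropic, the
acquisition resolution the workflow is designed around; surface meshes
are built from a finer (1 mm) re-voxelization of the same analytic
geometry, mirroring the higher-resolution anatomical scan used for
segmentation.

`synthesizeTracts()` emulates tractography output directly: 100 straight
polylines along the fascicle direction through a small mid-muscle
region, each end receded by a configurable truncation (tractography
stops short of the boundary) and jittered with Gaussian endpoint noise.
This gives fast, distribution-controlled input for estimator studies
without running the tracker.

The phantom deliberately does **not** simulate MR physics, speckle,
fascicle curvature, bipennate or multi-compartment geometry, or
through-plane fascicle dispersion. Passing tests therefore demonstrate
that the *computational chain* is correct and well-conditioned under
controlled perturbations — not that the method is accurate on real
muscle, where curvature (straight-line FL underestimates curved tracts)
and segmentation error add biases the phantom cannot expose.

Grid and cohort sizes used by the test-suite studies (a 3 × 3 grid of
thickness {8, 12, 16} mm × pennation {15, 30, 45}°, 100 tracts per
bundle, 20 noise replicates, 7-subject synthetic cohorts) were chosen to
match the scale of the emulated study design.

## Tracking

`trackStreamlines()` re-implements deterministic muscle tractography
with the protocol's settings as defaults: FA window [0.1, 0.7], maximum
inter-segment turn 10°, retained arc length 20–200 mm, step 1.0 mm, 100
seeds per region. Three choices deserve justification:

* **FA window reading.** Protocol listings of muscle-tractography FA
  windows sometimes transpose the two bounds, which read literally is
  vacuous. We adopt the standard reading 0.1 ≤ FA ≤ 0.7; both bounds are
  configurable.
* **Tensor interpolation.** Nearest-voxel lookup, not trilinear. The
  phantom fields are piecewise constant, so nearest-voxel is exact
  there, and the choice is documented so results are reproducible; it is
  the main source of the sub-voxel endpoint quantization discussed
  below.
* **Eigenvector sign.** The principal eigenvector is defined up to
  sign; each step aligns it with the previous step direction, and the
  first step with a reference axis (+y by default). Tracking runs in
  both directions from each seed.

The 20 mm minimum-length filter is a clinical setting: human fascicles
shorter than 20 mm are rare, but the validation grid intentionally
contains phantoms with FL down to ~11 mm (8 mm thickness at 45°), which
that filter would discard wholesale. The grid studies therefore track
with a 5 mm minimum while the default stays 20 mm; this is a phantom-
scale choice, not a recommendation for patient data.

## Meshing

`meshFromLabelMap()` extracts the 0.5-isosurface of the binary label
map. We use marching tetrahedra (each grid cell split into six
tetrahedra around its main diagonal): it produces the same class of
piecewise-linear isosurface as marching cubes but with unambiguous
per-tetrahedron cases and a guaranteed watertight result. Two smoothing
stages follow:

* a Gaussian pre-smoothing of the binary indicator (σ = 1 voxel by
  default) positions the isosurface at the true boundary for planar
  faces — a symmetric kernel cannot displace a flat interface — and
  removes the voxel staircase at its source;
* shrink-free Taubin smoothing of the mesh. The user-facing smoothing
  factor maps directly to the positive step λ, with the negative step
  derived from a fixed passband k_pb = 0.1 via 1/λ + 1/μ = k_pb (so
  factor 0.5 gives the classic λ = 0.5, μ ≈ −0.53 pair). Shrink-free
  smoothing matters because t_m is read off this surface; a shrinking
  smoother would bias thickness low.

Decimation (vertex clustering) exists but defaults to off: the amount of
"triangle reduction" in the emulated workflow is unstated, and *off* is
the conservative, reproducible choice. Normals are made outward by the
sign of the enclosed volume. Foreground touching the volume border is an
error instructing the user to pad, rather than silently producing an
open surface.

With integer-multiple thicknesses the phantom's voxel centers are laid
out so the digitized boundary coincides with the analytic plane; a
non-integer thickness (11.6 mm at 1 mm voxels) digitizes to the nearest
half-voxel, which is the familiar ±half-voxel quantization of any
voxelized surface and is visible in the worked example.

## DTI architecture measurement

`measureDti()` follows the median-endpoint reduction: tracts are
oriented along the bundle's mean direction; the two endpoint clouds are
reduced to component-wise medians; the median endpoints are extended
along their connecting line until the surface is intersected (rays are
cast from the line's midpoint, which is equivalent for interior
endpoints and stays well-defined when tracking overshoots the
triangulated surface by a fraction of a voxel); FL is the Euclidean
distance between the surface points. Pennation is measured per surface
triangle within 5 mm of each endpoint as the angle between the median
line and the triangle's *tangent plane* (90° minus the angle to the
normal), area-weighted. Some protocol descriptions phrase this step as
the angle to the surface normals; read literally that would complement
every reported angle, so the tangent-plane convention — the field's
standard definition of pennation — is the default and the literal
reading is available via `complement = FALSE`. Angles are sign-folded into [0°, 90°]; pennation
is unsigned.

Muscle thickness is measured computationally (replacing a manual ruler
step): rays are cast through the muscle along the depth axis at three
stations spaced 5 mm along the long axis around the measurement site,
and the three deep-to-superficial distances are averaged.

Bundles whose tracts "do not show a consistent pattern" are excluded:
consistency is the mean pairwise acute angle between tract end-to-end
directions, with a default threshold of 20°. The emulated workflow does
not quantify its exclusion criterion, so this threshold is an explicit,
configurable stand-in; results report the per-bundle angle so the
decision is auditable. If all bundles fail, a structured excluded-muscle
result is returned rather than an error — exclusion is a legitimate
study outcome.

One property worth knowing: the component-wise median is not
rotation-equivariant, so under endpoint noise the estimate can shift by
a fraction of the noise sd when the whole scene is rigidly rotated. For
noiseless bundles the estimator is exactly equivariant (the tests assert
this), and under 1 mm jitter the induced wobble is well below the
estimator's own sampling noise.

## Ultrasound model and frame alignment

`usMeasure()` computes, per digitized fascicle: PA_deep and PA_sup as
acute angles to the two aponeurosis lines; t_m as the distance between
the aponeurosis lines at the fascicle midpoint's lateral position
(perpendicular to the deep line by default; a vertical-in-image mode is
provided because the emulated workflow does not state which was used);
and FL = t_m / sin(PA_deep). Up to three fascicles are averaged, and the
reported PA is the mean of the averaged deep and superficial angles.
With non-parallel aponeuroses the deep line is the FL reference, the
superficial line enters only the PA average.

`projectPhantomToPlane()` creates the synthetic analogue of an acquired
image: aponeurosis planes intersected with the scan plane give the 2D
lines; three fascicle segments are placed at evenly spaced in-slab
positions along the projected fascicle direction. When the plane
contains the fascicle direction the measurement is exact; yawing the
probe by φ about the depth axis inflates the apparent angle as
tan(PA′) = tan(PA)/cos φ, the classic misalignment sensitivity, which
the tests verify against the closed form.

`fitRigidTransform()` is a Kabsch/SVD orthogonal Procrustes fit with a
reflection guard; only the four-marker skin cluster drives the fit (the
other markers are anatomical context). The probe plane is rebuilt in MR
space from the transformed transducer markers: lateral axis from AL to
AR (the 38 mm acquisition window), depth axis in-plane away from the
probe-body marker AU, field of view 40 mm deep by default (the imaging
depth is not stated in the emulated protocol; it is configurable).
Seeding for comparison with ultrasound happens on the in-FOV plane–mesh
cross-section: by default three seed spheres (radius 2.5 mm, one
acquisition voxel) at the centroids of equal lateral slices of the
cross-section polygon — the emulated workflow says only "at the site of
the intersection", so a deterministic rule is required, and evenly
spaced sites match its use of three seed regions per muscle.

## Statistics

`wilcoxonSignedRank()` implements the classic signed-rank test: zero
differences dropped (Pratt handling by flag), mid-ranks under ties, and
for n ≤ 25 an exact two-sided p over all 2ⁿ sign assignments, computed
by generating-function convolution in half-rank units — identical to
full enumeration (the tests check this against a literal 2ⁿ oracle) but
O(n · n²) instead of exponential. Two-sided p doubles the smaller tail
and caps at 1; a tie- and continuity-corrected normal approximation
takes over at larger n. The exact test is conservative at n = 7 (the
smallest attainable two-sided p is 2/128 ≈ 0.016), which the null-
calibration tests verify both analytically and by simulation.

Height normalization divides mm values by height in mm; the emulated
analysis does not state its units, and any positive scaling leaves
rank-based statistics unchanged (asserted in tests), so the
unit-consistent dimensionless choice is safe. BMI is weight/height² with
half-up rounding to one decimal, matching participant-table convention.

`compareMethods()` assembles the cohort report: per muscle × parameter,
median (min, max) per method, exact Wilcoxon p with a significance flag
at 0.05, and the mean (SD) within-subject absolute difference, run on
raw values and with FL and t_m height-normalized.

## The end-to-end study

`runEndToEnd()` chains every stage from one master seed and writes all
intermediate artifacts; identical (config, seed) reproduces the report
byte for byte. Its synthetic cohort gives each subject a slab geometry
drawn from gastrocnemius-like ranges (thickness 8–16 mm, pennation
15–35°), and models the two dominant, physically interpretable sources
of US–DTI disagreement: probe compression (the transducer thins the
muscle by ~1 mm; fascicle length is conserved, so the apparent angle
falls as asin(t′/FL)) and transducer yaw (Gaussian, sd 10°). These
defaults produce the qualitative pattern the comparison is designed to
detect — systematically different PA and t_m with broadly agreeing FL —
without asserting anything about effect sizes in real patients. The
default single-subject slab (12 mm, 25°) sits mid-range and its 28.4 mm
fascicle clears the 20 mm tract filter with margin.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based in all affine maps (NIfTI convention); world
  coordinates are always mm. One affine is the single source of the
  voxel-to-world mapping per volume.
* Ray–triangle tests use Möller–Trumbore with a 1e-9 parametric
  tolerance; an independent plane-plus-barycentric oracle checks them in
  the tests. Ray misses are values (`NULL`), not errors, except where a
  miss makes the requested measurement undefined.
* Cross-section stitching welds segment endpoints at 1e-6 mm; closed
  polygons are detected by end-to-start coincidence at that tolerance.
* Angles near 0 computed through `acos` carry the usual square-root
  precision floor (~1e-6 degrees); tests assert against that floor, not
  against 0.
* Degenerate requests error early with actionable messages: empty label
  maps, foreground on the volume border, collinear marker clusters,
  fascicles parallel to the deep aponeurosis (FL undefined), scan planes
  parallel to the aponeuroses, thickness rays that miss the surface,
  and all-zero paired differences.

## Known limitations

Straight-fascicle phantoms cannot probe curvature-induced FL
underestimation; the consistency threshold and FOV depth are declared
stand-ins for unquantified protocol details; vertex-clustering
decimation is coarse and off by default; the marching-tetrahedra surface
has roughly twice the triangle count of a marching-cubes surface at
equal resolution (harmless here, but worth knowing for very large
volumes); and the US observation model reduces operator variability to
yaw plus compression, which is the right first-order model but not a
speckle-level simulation.
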