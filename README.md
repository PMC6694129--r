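# muscleArch

Reconstruction and comparison of pennate muscle architecture *in vivo*:
fascicle length (FL), pennation angle (PA) and muscle thickness (t_m)
from diffusion-tensor tractography (DTI) and from 2D ultrasound (US),
with the rigid marker-based registration that places a tracked
ultrasound scan plane inside MR space, and the paired statistics used to
compare the two methods.

The package is aimed at researchers in muscle imaging and biomechanics
who want a tested, scriptable reimplementation of the DTI-based
architecture workflow — segmentation label map → surface mesh →
streamline tractography → median-endpoint fascicle reconstruction — and
of the ultrasound measurement model it is compared against. Because
patient imaging data for this kind of study are rarely shareable, the
package ships a synthetic phantom generator whose ground truth is
analytic, so every stage can be validated end to end.

## The model

A unipennate muscle compartment is idealized as the slab between two
parallel aponeurosis planes a distance t_m apart, with straight
fascicles at angle PA to the aponeuroses, so that

    FL = t_m / sin(PA)

holds exactly. On the DTI side, deterministic streamlines are integrated
with fixed 1.0 mm Euler steps along the principal eigenvector of the
local diffusion tensor, stopping when the fractional anisotropy
FA = sqrt(3/2)·‖λ − λ̄‖/‖λ‖ leaves the window [0.1, 0.7], the
inter-segment turn exceeds 10°, or the volume is left; tracts with arc
length outside [20, 200] mm are discarded. A bundle of 100 tracts is
reduced to the component-wise medians of its two endpoint clouds; the
median endpoints are extended along their connecting line to the muscle
surface mesh, FL is the Euclidean distance between the two surface
points, and the deep/superficial PAs are measured against the
area-weighted surface normals within 5 mm of each endpoint. On the US
side, PA is the angle between a digitized fascicle segment and the
aponeurosis lines, t_m the distance between the aponeurosis lines, and
FL = t_m / sin(PA_deep). US and MR frames are linked by an orthogonal
Procrustes (Kabsch) fit on a four-marker cluster, and the probe's scan
plane is rebuilt in MR space from three transducer markers. Paired
US-vs-DTI differences are tested with the exact Wilcoxon signed-rank
test (full sign-assignment enumeration at small n).

## Worked example

```r
library(muscleArch)

# a gastrocnemius-like phantom: 11.6 mm thick, 29.3 deg pennation
spec <- phantomSpec(thicknessMm = 11.6, pennationDeg = 29.3,
                    muscleLengthMm = 90, endpointJitterSdMm = 1)
ph <- makeUnipennatePhantom(spec)
ph
#> Unipennate phantom: t_m 11.60 mm, PA 29.30 deg, FL 23.70 mm; grid 22 x 42 x 11

# surface mesh from a 1 mm re-voxelization of the label map
lm <- phantomLabelMap(ph, voxelSizeMm = 1)
mesh <- meshFromLabelMap(lm$labels, lm$affine)

# locate the tracked US plane in MR space and seed tracking at the
# plane-muscle intersection (three sites along the intersection)
plane <- locateUsPlaneInMr(makeMarkerScene(rigidTransform()))
seeds <- seedFromIntersection(plane, mesh, nSites = 3)
bundles <- lapply(seq_along(seeds), function(i)
  trackStreamlines(ph@tensorVolume, seeds[[i]], trackingParams(),
                   rngSeed = i))
bundles[[1]]
#> TractBundle: 100 tracts, arc length 24.0-25.0 mm

measureDti(bundles, mesh)
#> ArchitectureResult [phantom, DTI]: FL 24.55 mm, PA 29.26 deg (deep 29.26, sup 29.26), t_m 12.00 mm

# the same phantom seen by an in-plane ultrasound scan
usMeasure(projectPhantomToPlane(ph, plane))
#> ArchitectureResult [phantom, US]: FL 23.70 mm, PA 29.30 deg (deep 29.30, sup 29.30), t_m 11.60 mm

# paired comparison of seven US vs DTI pennation angles
wilcoxonSignedRank(c(14.2, 22.0, 29.3, 30.1, 31.6, 33.4, 34.8),
                   c(7.8, 11.9, 13.4, 13.9, 14.6, 15.8, 16.1))
#> Wilcoxon signed-rank: W = 28.0, n = 7, two-sided p = 0.015625 (exact)
```

Reading the numbers: the DTI estimate recovers the 23.70 mm ground-truth
fascicle length to within ~0.9 mm under 1 mm endpoint jitter, and the
pennation angle to within 0.05°. The thickness reads 12.0 rather than
11.6 mm because an 11.6 mm slab digitized at 1 mm voxels has its
boundary at the nearest half-voxel — the expected half-voxel
quantization of a voxelized surface. The in-plane ultrasound view of the
same phantom is exact by construction; the exact signed-rank p of 2/128
is the smallest two-sided p attainable with seven pairs.

`runEndToEnd(pipelineConfig(), seed = 1)` chains all of the above —
phantom, meshing, marker alignment, seeding, tracking, DTI and US
measurement — and then simulates a small cohort whose US arm includes
probe compression and transducer yaw, comparing the two methods with
exact Wilcoxon tests (raw and height-normalized).

A thin command-line wrapper with subcommands (`phantom`, `track`,
`measure-dti`, `measure-us`, `align`, `compare`, `run-all`) is installed
at `inst/scripts/muscle-arch.R`.

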