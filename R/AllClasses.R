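#' @import methods
#' @importFrom stats median sd pnorm rnorm runif uniroot setNames
#' @importFrom utils read.csv write.csv head tail
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Rigid transform between two world frames
#'
#' A proper rigid-body transform (rotation + translation, no scaling or
#' reflection) mapping points from a source frame to a destination frame,
#' as fitted from marker correspondences. Units are mm.
#'
#' @slot rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @slot translation length-3 numeric translation (mm).
#' @slot rmsResidual root-mean-square fit residual (mm) over the markers
#'   used for the fit; 0 for exact/constructed transforms.
#'
#' @seealso [fitRigidTransform()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 rmsResidual = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), rmsResidual = 0)
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (R'R = I)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det = +1, no reflection)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (length(object@rmsResidual) != 1L || object@rmsResidual < 0)
    return("rmsResidual must be a nonnegative scalar")
  TRUE
})

setClassUnion("RigidTransformOrNULL", c("RigidTransform", "NULL"))

#' Voxel grid of diffusion tensors
#'
#' Holds one symmetric 3x3 diffusion tensor per voxel plus the voxel-to-world
#' affine. Tensors are stored as a 4D array whose last dimension carries the
#' six unique components in lower-triangular order
#' `Dxx, Dxy, Dyy, Dxz, Dyz, Dzz` (mm^2/s), the same convention used by the
#' NIfTI writer.
#'
#' @slot dims integer length-3 grid dimensions.
#' @slot affine 4x4 voxel-index (0-based) to world-mm map.
#' @slot tensors numeric array `dims x 6`.
#'
#' @seealso [tensorAt()], [faVolume()], [trackStreamlines()]
#' @export
setClass("TensorVolume",
  representation(dims = "integer", affine = "matrix", tensors = "array"))

setValidity("TensorVolume", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be 3 positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be 4x4")
  if (abs(det(object@affine)) < .Machine$double.eps)
    return("affine must be invertible")
  if (!all(dim(object@tensors) == c(object@dims, 6L)))
    return("tensors must be an array of dim c(dims, 6)")
  TRUE
})

#' Spherical seed region for tractography
#'
#' @slot center world-mm center of the seed sphere.
#' @slot radius sphere radius in mm (> 0).
#' @export
setClass("SeedRegion",
  representation(center = "numeric", radius = "numeric"))

setValidity("SeedRegion", function(object) {
  if (length(object@center) != 3L) return("center must be length 3")
  if (length(object@radius) != 1L || object@radius <= 0)
    return("radius must be a positive scalar")
  TRUE
})

setClassUnion("SeedRegionOrNULL", c("SeedRegion", "NULL"))

#' Bundle of streamline tracts
#'
#' An ordered collection of 3D polylines (each an n x 3 matrix of world-mm
#' points) produced by tractography or by the phantom generator from one
#' seed region.
#'
#' @slot tracts list of n x 3 numeric matrices.
#' @slot seed the generating [SeedRegion-class], or `NULL`.
#' @slot nDiscarded number of candidate tracts removed by the length filter.
#' @slot emptyWarning `TRUE` when tracking retained no tracts (the bundle is
#'   returned empty rather than erroring, mirroring how an unusable muscle
#'   is excluded rather than aborting a study).
#' @seealso [trackStreamlines()], [synthesizeTracts()], [medianEndpoints()]
#' @export
setClass("TractBundle",
  representation(tracts = "list", seed = "SeedRegionOrNULL",
                 nDiscarded = "integer", emptyWarning = "logical"),
  prototype(seed = NULL, nDiscarded = 0L, emptyWarning = FALSE))

setValidity("TractBundle", function(object) {
  ok <- vapply(object@tracts, function(t)
    is.matrix(t) && ncol(t) == 3L && nrow(t) >= 2L && all(is.finite(t)),
    logical(1))
  if (!all(ok)) return("every tract must be a finite n x 3 matrix, n >= 2")
  TRUE
})

#' Triangulated muscle surface
#'
#' A triangle mesh in world mm with per-triangle unit normals oriented
#' outward (positive enclosed volume for watertight meshes).
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot triangles m x 3 integer matrix of 1-based vertex indices.
#' @slot normals m x 3 numeric matrix of unit triangle normals.
#' @seealso [meshFromLabelMap()], [rayMeshFirstHit()], [planeMeshIntersection()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 normals = "matrix"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
  if (nrow(object@triangles) < 1L) return("mesh has no triangles")
  idx <- range(object@triangles)
  if (idx[1L] < 1L || idx[2L] > nrow(object@vertices))
    return("triangle indices out of range")
  if (!all(dim(object@normals) == dim(object@triangles)))
    return("normals must match triangles in shape")
  len <- sqrt(rowSums(object@normals^2))
  if (any(abs(len - 1) > 1e-9)) return("normals must be unit length")
  TRUE
})

#' Oriented, bounded ultrasound scan plane
#'
#' The imaging plane of the ultrasound transducer, built from the three
#' probe markers AL, AR, AU. In-plane coordinates are (lateral, depth):
#' lateral runs from AL towards AR across the acquisition window, depth runs
#' perpendicular to it within the plane, away from the probe marker AU
#' (i.e. into the body). The field of view is the rectangle
#' lateral in [-fovWidth/2, fovWidth/2], depth in [0, fovDepth] about the
#' origin (the AL-AR midpoint).
#'
#' @slot origin world-mm point, midpoint of AL-AR.
#' @slot normal unit plane normal (lateral x depth, right-handed).
#' @slot lateral unit in-plane axis AL -> AR.
#' @slot depth unit in-plane axis, perpendicular to lateral, pointing away
#'   from AU.
#' @slot fovWidth acquisition-window width in mm (distance AL-AR).
#' @slot fovDepth imaging depth of the field of view in mm.
#' @seealso [scanPlaneFromProbe()], [locateUsPlaneInMr()],
#'   [planeMeshIntersection()]
#' @export
setClass("ScanPlane",
  representation(origin = "numeric", normal = "numeric", lateral = "numeric",
                 depth = "numeric", fovWidth = "numeric",
                 fovDepth = "numeric"))

setValidity("ScanPlane", function(object) {
  ax <- rbind(object@lateral, object@depth, object@normal)
  if (any(dim(ax) != c(3L, 3L))) return("axes must be length-3 vectors")
  if (max(abs(tcrossprod(ax) - diag(3))) > 1e-8)
    return("lateral/depth/normal must be orthonormal")
  if (object@fovWidth <= 0) return("fovWidth must be > 0")
  if (object@fovDepth <= 0) return("fovDepth must be > 0")
  TRUE
})

#' Muscle architecture parameters from one method
#'
#' The comparison unit of the package: fascicle length, deep/superficial/mean
#' pennation angle and muscle thickness for one muscle measured by one method
#' (2D ultrasound, DTI tractography, or phantom ground truth). An excluded
#' result (no consistent tract bundle) carries `excluded = TRUE` and NA
#' values.
#'
#' @slot flMm fascicle length (mm).
#' @slot paDeepDeg pennation angle at the deep aponeurosis (degrees).
#' @slot paSupDeg pennation angle at the superficial aponeurosis (degrees).
#' @slot paDeg reported pennation angle, the mean of deep and superficial.
#' @slot tmMm muscle thickness (mm).
#' @slot method one of "US", "DTI", "truth".
#' @slot muscle free-form muscle tag (e.g. "GA", "PSO", "TA", "phantom").
#' @slot excluded `TRUE` when the muscle was excluded (inconsistent bundles).
#' @seealso [measureDti()], [usMeasure()], [makeUnipennatePhantom()]
#' @export
setClass("ArchitectureResult",
  representation(flMm = "numeric", paDeepDeg = "numeric", paSupDeg = "numeric",
                 paDeg = "numeric", tmMm = "numeric", method = "character",
                 muscle = "character", excluded = "logical"),
  prototype(method = "truth", muscle = "phantom", excluded = FALSE))

setValidity("ArchitectureResult", function(object) {
  if (!object@method %in% c("US", "DTI", "truth"))
    return("method must be 'US', 'DTI' or 'truth'")
  if (object@excluded) return(TRUE)
  v <- c(object@flMm, object@paDeepDeg, object@paSupDeg, object@paDeg,
         object@tmMm)
  if (length(v) != 5L || !all(is.finite(v)) || any(v <= 0))
    return("all architecture values must be finite and positive")
  if (object@paDeg > 90 || object@paDeepDeg > 90 || object@paSupDeg > 90)
    return("pennation angles must lie in (0, 90] degrees")
  if (abs(object@paDeg - (object@paDeepDeg + object@paSupDeg) / 2) > 1e-6)
    return("paDeg must be the mean of deep and superficial angles")
  TRUE
})

#' Specification of a synthetic unipennate phantom
#'
#' Parameters of the slab phantom: a muscle compartment bounded by two
#' parallel aponeurosis planes a prescribed thickness apart, with straight
#' fascicles at a prescribed pennation angle, voxelized into a label map and
#' a diffusion-tensor field. Defaults follow the imaging protocol the
#' package emulates: 2.5 mm isotropic voxels and bundles of 100 tracts.
#'
#' @slot thicknessMm distance between the aponeurosis planes (mm).
#' @slot pennationDeg fascicle angle to the aponeurosis plane, in (0, 90].
#' @slot muscleLengthMm extent of the compartment along the line of action.
#' @slot widthMm medio-lateral extent of the compartment.
#' @slot voxelSizeMm isotropic voxel size (default 2.5).
#' @slot faInside fractional anisotropy of tensors inside the muscle
#'   (default 0.35, within the tracking FA window).
#' @slot faOutside fractional anisotropy outside (default 0.05, below the
#'   window, so streamlines stop at the muscle boundary).
#' @slot endpointJitterSdMm Gaussian sd of synthetic tract endpoint noise.
#' @slot truncationMm gap between synthetic tract ends and the aponeuroses,
#'   measured along the tract line.
#' @slot nTracts tracts per synthetic bundle (default 100).
#' @slot rngSeed integer seed for all phantom randomness.
#' @seealso [phantomSpec()], [makeUnipennatePhantom()], [synthesizeTracts()]
#' @export
setClass("PhantomSpec",
  representation(thicknessMm = "numeric", pennationDeg = "numeric",
                 muscleLengthMm = "numeric", widthMm = "numeric",
                 voxelSizeMm = "numeric", faInside = "numeric",
                 faOutside = "numeric", endpointJitterSdMm = "numeric",
                 truncationMm = "numeric", nTracts = "integer",
                 rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  s <- object
  if (s@thicknessMm <= 0) return("thicknessMm must be > 0")
  if (s@pennationDeg <= 0 || s@pennationDeg > 90)
    return("pennationDeg must lie in (0, 90]")
  if (s@muscleLengthMm <= 0 || s@widthMm <= 0)
    return("muscleLengthMm and widthMm must be > 0")
  if (s@thicknessMm >= s@muscleLengthMm)
    return("thicknessMm must be smaller than muscleLengthMm")
  if (s@voxelSizeMm <= 0) return("voxelSizeMm must be > 0")
  if (s@faInside <= 0 || s@faInside >= 1) return("faInside must be in (0,1)")
  if (s@faOutside < 0 || s@faOutside >= 1)
    return("faOutside must be in [0,1)")
  if (s@endpointJitterSdMm < 0) return("endpointJitterSdMm must be >= 0")
  if (s@truncationMm < 0) return("truncationMm must be >= 0")
  if (s@nTracts < 1L) return("nTracts must be >= 1")
  TRUE
})

#' Synthetic unipennate muscle phantom
#'
#' A voxelized slab muscle with analytic ground truth. The world frame is
#' right-handed in mm with the line of action along +y and depth along +z;
#' the deep aponeurosis is the plane of smaller z. By construction
#' `truth@flMm == truth@tmMm / sin(truth@paDeg)`.
#'
#' @slot labels integer 3D array, 1 inside the muscle compartment.
#' @slot affine 4x4 voxel-to-world map shared by labels and tensors.
#' @slot tensorVolume the [TensorVolume-class] over the same grid.
#' @slot deepPlane,supPlane lists with elements `point` and `normal`
#'   (outward unit normal) describing the analytic aponeurosis planes.
#' @slot truth ground-truth [ArchitectureResult-class] (method "truth").
#' @slot fascicleDirection unit 3-vector of the fascicle direction.
#' @slot spec the generating [PhantomSpec-class].
#' @seealso [makeUnipennatePhantom()]
#' @export
setClass("Phantom",
  representation(labels = "array", affine = "matrix",
                 tensorVolume = "TensorVolume", deepPlane = "list",
                 supPlane = "list", truth = "ArchitectureResult",
                 fascicleDirection = "numeric", spec = "PhantomSpec"))

setValidity("Phantom", function(object) {
  tr <- object@truth
  if (abs(tr@flMm - tr@tmMm / sin(.deg2rad(tr@paDeg))) > 1e-9)
    return("truth must satisfy FL = t_m / sin(PA)")
  if (abs(.vnorm(object@fascicleDirection) - 1) > 1e-9)
    return("fascicleDirection must be a unit vector")
  TRUE
})

#' Streamline tracking parameters
#'
#' Stopping and retention rules for deterministic streamline tractography.
#' Defaults reproduce the muscle-tractography settings the package emulates:
#' FA window [0.1, 0.7], maximum inter-segment turn 10 degrees, retained
#' tract length 20-200 mm, step size 1.0 mm, 100 tracts per seed region.
#' (Protocol listings of this FA window sometimes transpose its bounds;
#' the standard reading 0.1 <= FA <= 0.7 is used here and both bounds are
#' configurable.)
#'
#' @slot faMin,faMax fractional-anisotropy window for tracking.
#' @slot maxTurnDeg maximum angle between consecutive tract segments.
#' @slot minLenMm,maxLenMm arc-length retention window for whole tracts.
#' @slot stepMm integration step (mm).
#' @slot nTracts number of seed points drawn in the seed region.
#' @seealso [trackingParams()], [trackStreamlines()]
#' @export
setClass("TrackingParams",
  representation(faMin = "numeric", faMax = "numeric", maxTurnDeg = "numeric",
                 minLenMm = "numeric", maxLenMm = "numeric",
                 stepMm = "numeric", nTracts = "integer"))

setValidity("TrackingParams", function(object) {
  if (object@faMin < 0 || object@faMax > 1 || object@faMin >= object@faMax)
    return("need 0 <= faMin < faMax <= 1")
  if (object@maxTurnDeg <= 0) return("maxTurnDeg must be > 0")
  if (object@stepMm <= 0 || object@stepMm > object@minLenMm)
    return("need 0 < stepMm <= minLenMm")
  if (object@minLenMm >= object@maxLenMm)
    return("need minLenMm < maxLenMm")
  if (object@nTracts < 1L) return("nTracts must be >= 1")
  TRUE
})

#' Marker scene observed in the ultrasound and MR frames
#'
#' Coordinates of the skin-mounted marker cluster P1-P8 and the probe
#' markers AL, AR, AU, observed in the ultrasound (motion-capture) frame and
#' in the MR frame. For synthetic scenes the generating rigid transform is
#' retained as ground truth.
#'
#' @slot markers data.frame with columns `label`, `frame` ("US" or "MR"),
#'   `x_mm`, `y_mm`, `z_mm`.
#' @slot trueTransform the generating [RigidTransform-class] (US -> MR), or
#'   `NULL` for observed data.
#' @seealso [makeMarkerScene()], [locateUsPlaneInMr()]
#' @export
setClass("MarkerScene",
  representation(markers = "data.frame",
                 trueTransform = "RigidTransformOrNULL"),
  prototype(trueTransform = NULL))

setValidity("MarkerScene", function(object) {
  need <- c("label", "frame", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(object@markers)))
    return(paste("markers must have columns", paste(need, collapse = ", ")))
  if (!all(object@markers$frame %in% c("US", "MR")))
    return("frame must be 'US' or 'MR'")
  TRUE
})

#' Annotated 2D ultrasound scene
#'
#' The geometric content of a manually digitized B-mode image: the deep and
#' superficial aponeurosis lines and one to three fascicle segments, in
#' image-plane mm coordinates (x lateral, y depth; larger y = deeper).
#'
#' @slot apoDeep,apoSup 2 x 2 matrices, one endpoint per row (x, y).
#' @slot fascicles list of 1-3 such 2 x 2 matrices.
#' @seealso [usScene2D()], [usMeasure()], [projectPhantomToPlane()]
#' @export
setClass("UsScene2D",
  representation(apoDeep = "matrix", apoSup = "matrix", fascicles = "list"))

setValidity("UsScene2D", function(object) {
  seg <- function(m) is.matrix(m) && all(dim(m) == c(2L, 2L)) &&
    all(is.finite(m)) && sum((m[1L, ] - m[2L, ])^2) > 1e-12
  if (!seg(object@apoDeep) || !seg(object@apoSup))
    return("aponeurosis segments must be non-degenerate 2 x 2 matrices")
  if (length(object@fascicles) < 1L || length(object@fascicles) > 3L)
    return("need 1 to 3 fascicle segments")
  if (!all(vapply(object@fascicles, seg, logical(1))))
    return("fascicle segments must be non-degenerate 2 x 2 matrices")
  dMid <- mean(object@apoDeep[, 2L]); sMid <- mean(object@apoSup[, 2L])
  if (dMid <= sMid)
    return("deep aponeurosis must lie at greater depth than superficial")
  TRUE
})

#' Tract-bundle consistency summary
#'
#' Mean pairwise angle between the end-to-end directions of the tracts of a
#' bundle, and the derived consistency flag used to exclude bundles whose
#' tracts do not show a consistent pattern.
#'
#' @slot meanPairwiseAngleDeg mean pairwise line angle (degrees).
#' @slot consistent `TRUE` iff the mean angle is at most `thresholdDeg`.
#' @slot thresholdDeg exclusion threshold in degrees (default 20; manual
#'   workflows judge consistency by eye, so an explicit configurable
#'   threshold stands in for that judgement).
#' @seealso [bundleConsistency()], [measureDti()]
#' @export
setClass("BundleQuality",
  representation(meanPairwiseAngleDeg = "numeric", consistent = "logical",
                 thresholdDeg = "numeric"))

setValidity("BundleQuality", function(object) {
  if (object@meanPairwiseAngleDeg < 0)
    return("meanPairwiseAngleDeg must be >= 0")
  if (object@consistent != (object@meanPairwiseAngleDeg <= object@thresholdDeg))
    return("consistent flag must equal meanPairwiseAngleDeg <= thresholdDeg")
  TRUE
})
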