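# Constructors, accessors and show() methods for the core S4 containers.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (default identity).
#' @param translation length-3 translation in mm (default zero).
#' @param rmsResidual fit residual to record (default 0).
#' @return A [RigidTransform-class].
#' @examples
#' tr <- rigidTransform(translation = c(10, 20, 30))
#' applyTransform(tr, c(0, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           rmsResidual = 0) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation),
      rmsResidual = as.numeric(rmsResidual))
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points a length-3 vector or n x 3 matrix of world-mm points.
#' @return Points in the destination frame, same shape as the input.
#' @export
applyTransform <- function(transform, points) {
  stopifnot(is(transform, "RigidTransform"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1L, 3L) else as.matrix(points)
  out <- pts %*% t(transform@rotation) +
    matrix(transform@translation, nrow(pts), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class] (destination -> source).
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -drop(Rt %*% transform@translation),
                 transform@rmsResidual)
}

#' Construct a tensor volume
#'
#' @param tensors 4D array `nx x ny x nz x 6`, six unique tensor components
#'   per voxel in lower-triangular order `Dxx, Dxy, Dyy, Dxz, Dyz, Dzz`.
#' @param affine 4x4 map from 0-based voxel index to world mm (NIfTI
#'   convention).
#' @return A [TensorVolume-class].
#' @export
tensorVolume <- function(tensors, affine) {
  new("TensorVolume", dims = as.integer(dim(tensors)[1:3]),
      affine = affine, tensors = tensors)
}

#' Extract the symmetric 3x3 tensor at one voxel
#'
#' @param vol a [TensorVolume-class].
#' @param i,j,k 1-based voxel indices.
#' @return A symmetric 3x3 matrix (mm^2/s).
#' @export
tensorAt <- function(vol, i, j, k) {
  v <- vol@tensors[i, j, k, ]
  matrix(c(v[1L], v[2L], v[4L],
           v[2L], v[3L], v[5L],
           v[4L], v[5L], v[6L]), 3L, 3L)
}

#' Construct a seed region
#'
#' @param center world-mm center.
#' @param radius sphere radius in mm.
#' @return A [SeedRegion-class].
#' @export
seedRegion <- function(center, radius) {
  new("SeedRegion", center = as.numeric(center), radius = as.numeric(radius))
}

#' Construct a tract bundle
#'
#' @param tracts list of n x 3 matrices of world-mm points.
#' @param seed optional generating [SeedRegion-class].
#' @param nDiscarded number of tracts removed by filters.
#' @param emptyWarning flag set when tracking retained nothing.
#' @return A [TractBundle-class].
#' @export
tractBundle <- function(tracts, seed = NULL, nDiscarded = 0L,
                        emptyWarning = FALSE) {
  new("TractBundle", tracts = tracts, seed = seed,
      nDiscarded = as.integer(nDiscarded), emptyWarning = emptyWarning)
}

#' Number of tracts in a bundle
#' @param bundle a [TractBundle-class].
#' @return Integer count.
#' @export
nTracts <- function(bundle) length(bundle@tracts)

#' Arc lengths of the tracts of a bundle
#' @param bundle a [TractBundle-class].
#' @return Numeric vector of polyline arc lengths (mm).
#' @export
tractLengths <- function(bundle) {
  vapply(bundle@tracts, function(t) {
    if (nrow(t) < 2L) return(0)
    sum(sqrt(rowSums((t[-1L, , drop = FALSE] -
                        t[-nrow(t), , drop = FALSE])^2)))
  }, numeric(1))
}

#' Construct a surface mesh
#'
#' Normals are recomputed from the triangle winding; if the mesh encloses a
#' negative signed volume all triangles are flipped so normals point
#' outward.
#'
#' @param vertices n x 3 matrix of vertex positions (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return A [SurfaceMesh-class].
#' @export
surfaceMesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  m <- .dropDegenerate(vertices, triangles)
  if (.meshSignedVolume(m$vertices, m$triangles) < 0)
    m$triangles <- m$triangles[, c(1L, 3L, 2L), drop = FALSE]
  new("SurfaceMesh", vertices = m$vertices, triangles = m$triangles,
      normals = .triangleNormals(m$vertices, m$triangles))
}

#' Total surface area of a mesh
#' @param mesh a [SurfaceMesh-class].
#' @return Area in mm^2.
#' @export
meshArea <- function(mesh) sum(.triangleAreas(mesh@vertices, mesh@triangles))

#' Signed enclosed volume of a mesh
#' @param mesh a [SurfaceMesh-class].
#' @return Volume in mm^3 (positive for outward-oriented watertight meshes).
#' @export
meshVolume <- function(mesh) .meshSignedVolume(mesh@vertices, mesh@triangles)

#' Ground-truth architecture of a phantom
#' @param phantom a [Phantom-class].
#' @return The [ArchitectureResult-class] with method "truth".
#' @export
groundTruth <- function(phantom) phantom@truth

#' Construct an architecture result
#'
#' The reported pennation angle is always the mean of the deep and
#' superficial angles.
#'
#' @param flMm fascicle length (mm).
#' @param paDeepDeg,paSupDeg deep and superficial pennation angles (deg).
#' @param tmMm muscle thickness (mm).
#' @param method "US", "DTI" or "truth".
#' @param muscle muscle tag.
#' @param excluded set `TRUE` (with NA values) for an excluded muscle.
#' @return An [ArchitectureResult-class].
#' @export
architectureResult <- function(flMm, paDeepDeg, paSupDeg, tmMm,
                               method = "DTI", muscle = "phantom",
                               excluded = FALSE) {
  if (excluded)
    return(new("ArchitectureResult", flMm = NA_real_, paDeepDeg = NA_real_,
               paSupDeg = NA_real_, paDeg = NA_real_, tmMm = NA_real_,
               method = method, muscle = muscle, excluded = TRUE))
  new("ArchitectureResult", flMm = flMm, paDeepDeg = paDeepDeg,
      paSupDeg = paSupDeg, paDeg = (paDeepDeg + paSupDeg) / 2, tmMm = tmMm,
      method = method, muscle = muscle, excluded = FALSE)
}

#' Architecture result as a one-row data frame
#' @param result an [ArchitectureResult-class].
#' @return data.frame with columns muscle, method, FL_mm, PA_deep_deg,
#'   PA_sup_deg, PA_deg, t_m_mm, excluded.
#' @export
asArchitectureRow <- function(result) {
  data.frame(muscle = result@muscle, method = result@method,
             FL_mm = result@flMm, PA_deep_deg = result@paDeepDeg,
             PA_sup_deg = result@paSupDeg, PA_deg = result@paDeg,
             t_m_mm = result@tmMm, excluded = result@excluded,
             stringsAsFactors = FALSE)
}

#' Construct a 2D ultrasound scene
#'
#' @param apoDeep,apoSup 2 x 2 matrices (one endpoint per row, columns x
#'   lateral / y depth in image mm) for the deep and superficial
#'   aponeurosis lines. Larger y is deeper.
#' @param fascicles a single 2 x 2 matrix or a list of 1-3 of them.
#' @return A [UsScene2D-class].
#' @export
usScene2D <- function(apoDeep, apoSup, fascicles) {
  if (is.matrix(fascicles)) fascicles <- list(fascicles)
  new("UsScene2D", apoDeep = apoDeep, apoSup = apoSup, fascicles = fascicles)
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (US -> MR style, mm)\n")
  cat("  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 4), collapse = ", "),
      "\n  rms residual:", format(object@rmsResidual, digits = 4), "mm\n")
})

setMethod("show", "TensorVolume", function(object) {
  cat("TensorVolume:", paste(object@dims, collapse = " x "),
      "voxels, voxel size ~",
      paste(round(sqrt(colSums(object@affine[1:3, 1:3]^2)), 3),
            collapse = " x "), "mm\n")
})

setMethod("show", "TractBundle", function(object) {
  n <- nTracts(object)
  cat("TractBundle:", n, "tracts")
  if (n > 0L) {
    len <- tractLengths(object)
    cat(sprintf(", arc length %.1f-%.1f mm", min(len), max(len)))
  }
  if (object@nDiscarded > 0L) cat(",", object@nDiscarded, "discarded")
  if (object@emptyWarning) cat(" [warning: empty bundle]")
  cat("\n")
})

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles, area",
      sprintf("%.1f mm^2,", meshArea(object)), "volume",
      sprintf("%.1f mm^3\n", meshVolume(object)))
})

setMethod("show", "ScanPlane", function(object) {
  cat("ScanPlane: origin (", paste(round(object@origin, 2), collapse = ", "),
      "), normal (", paste(round(object@normal, 4), collapse = ", "),
      sprintf("), FOV %.1f x %.1f mm\n", object@fovWidth, object@fovDepth))
})

setMethod("show", "ArchitectureResult", function(object) {
  if (object@excluded) {
    cat(sprintf("ArchitectureResult [%s, %s]: muscle excluded\n",
                object@muscle, object@method))
  } else {
    cat(sprintf(
      "ArchitectureResult [%s, %s]: FL %.2f mm, PA %.2f deg (deep %.2f, sup %.2f), t_m %.2f mm\n",
      object@muscle, object@method, object@flMm, object@paDeg,
      object@paDeepDeg, object@paSupDeg, object@tmMm))
  }
})

setMethod("show", "Phantom", function(object) {
  tr <- object@truth
  cat(sprintf(
    "Unipennate phantom: t_m %.2f mm, PA %.2f deg, FL %.2f mm; grid %s\n",
    tr@tmMm, tr@paDeg, tr@flMm, paste(dim(object@labels), collapse = " x ")))
})

setMethod("show", "BundleQuality", function(object) {
  cat(sprintf("BundleQuality: mean pairwise angle %.2f deg (threshold %.1f) -> %s\n",
              object@meanPairwiseAngleDeg, object@thresholdDeg,
              if (object@consistent) "consistent" else "inconsistent"))
})
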