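# DTI-based architecture measurement: reduce a tract bundle plus the
# muscle surface mesh to fascicle length, deep/superficial pennation
# angles and muscle thickness, with a consistency check that excludes
# unusable bundles.

#' Median endpoints of a tract bundle
#'
#' Orients every tract along the bundle's mean end-to-end direction, then
#' takes the component-wise median of the endpoints at either end. The end
#' whose median has the smaller coordinate along `depthAxis` is labelled
#' deep.
#'
#' @param bundle a non-empty [TractBundle-class].
#' @param depthAxis unit vector pointing from deep to superficial (default
#'   +z, the phantom convention; real data supply the axis).
#' @return List with `deep` and `sup`, each a world-mm point.
#' @export
medianEndpoints <- function(bundle, depthAxis = c(0, 0, 1)) {
  n <- nTracts(bundle)
  if (n == 0L) stop("cannot take median endpoints of an empty bundle")
  firsts <- t(vapply(bundle@tracts, function(t) t[1L, ], numeric(3)))
  lasts <- t(vapply(bundle@tracts, function(t) t[nrow(t), ], numeric(3)))
  dirs <- lasts - firsts
  ref <- dirs[1L, ]
  flip <- drop(dirs %*% ref) < 0
  dirs[flip, ] <- -dirs[flip, ]
  m <- colMeans(dirs)
  flip <- drop((lasts - firsts) %*% m) < 0
  tmp <- firsts[flip, , drop = FALSE]
  firsts[flip, ] <- lasts[flip, , drop = FALSE]
  lasts[flip, ] <- tmp
  e1 <- apply(firsts, 2L, median)
  e2 <- apply(lasts, 2L, median)
  if (sum(e1 * depthAxis) <= sum(e2 * depthAxis))
    list(deep = e1, sup = e2)
  else
    list(deep = e2, sup = e1)
}

#' Extend median endpoints to the muscle surface
#'
#' Translates each median endpoint towards the muscle surface along the
#' line connecting both endpoints until the surface is intersected: the
#' deep endpoint moves along `eDeep - eSup`, the superficial endpoint
#' along `eSup - eDeep`. The rays are cast from the midpoint of the
#' median line (inside the muscle), which is equivalent for interior
#' endpoints and remains well-defined when an endpoint sits exactly on,
#' or a fraction of a voxel beyond, the triangulated surface. Endpoints
#' already on the surface are returned unchanged.
#'
#' @param eDeep,eSup median endpoints (world mm); must differ.
#' @param mesh a [SurfaceMesh-class].
#' @return List with `deep` and `sup` surface points.
#' @export
extendToSurface <- function(eDeep, eSup, mesh) {
  if (.vnorm(eDeep - eSup) < 1e-9)
    stop("median endpoints coincide; cannot define the fascicle line")
  dDeep <- .unitv(eDeep - eSup)
  mid <- (eDeep + eSup) / 2
  cast <- function(dir, side) {
    hit <- rayMeshFirstHit(mesh, mid, dir, tol = 1e-9)
    if (is.null(hit))
      stop(sprintf("the %s endpoint ray does not intersect the surface",
                   side))
    hit$point
  }
  list(deep = cast(dDeep, "deep"), sup = cast(-dDeep, "superficial"))
}

#' Fascicle length from the two surface endpoints
#'
#' Euclidean distance between the deep and superficial endpoint; the
#' straight-line approximation of the fascicle path.
#'
#' @param pDeep,pSup world-mm surface points.
#' @return Length in mm.
#' @export
fascicleLength <- function(pDeep, pSup) .vnorm(pSup - pDeep)

#' Pennation angle of a fascicle direction against the local surface
#'
#' For every triangle whose centroid lies within `radiusMm` of the
#' endpoint, computes the angle between the fascicle direction and the
#' triangle's tangent plane (90 degrees minus the acute angle to the
#' normal; directions are sign-folded so the result lies in \[0, 90\])
#' and returns the area-weighted average. Set `complement = FALSE` to
#' report the raw angle to the normals instead.
#'
#' @param tractDir unit fascicle direction.
#' @param mesh a [SurfaceMesh-class].
#' @param endpoint world-mm surface point.
#' @param radiusMm triangle-inclusion radius (default 5).
#' @param areaWeighted area-weight the per-triangle angles (default).
#' @param complement report the angle to the tangent plane (default) or
#'   to the normal.
#' @return Angle in degrees.
#' @export
pennationFromNormals <- function(tractDir, mesh, endpoint, radiusMm = 5,
                                 areaWeighted = TRUE, complement = TRUE) {
  ctr <- .triangleCentroids(mesh@vertices, mesh@triangles)
  d2 <- rowSums(sweep(ctr, 2L, endpoint)^2)
  sel <- d2 <= radiusMm^2
  if (!any(sel))
    stop(sprintf(
      "no triangle centroid within %.3g mm of the endpoint; use a larger radius",
      radiusMm))
  dirU <- .unitv(tractDir)
  cosToNormal <- abs(drop(mesh@normals[sel, , drop = FALSE] %*% dirU))
  angToNormal <- .rad2deg(acos(.clamp(cosToNormal, 0, 1)))
  ang <- if (complement) 90 - angToNormal else angToNormal
  w <- if (areaWeighted)
    .triangleAreas(mesh@vertices, mesh@triangles)[sel] else rep(1, sum(sel))
  sum(w * ang) / sum(w)
}

#' Muscle thickness along the depth direction, averaged over stations
#'
#' At `nStations` points spaced `stationSpacingMm` apart along the
#' muscle's long axis around `station`, casts a ray through the muscle
#' along `direction` (deep to superficial) and averages the deep-to-
#' superficial surface distances. `station` should lie inside the muscle;
#' the two surface crossings are found by casting in both directions.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param station world-mm point inside the muscle at the measurement
#'   site.
#' @param direction unit vector from deep to superficial surface.
#' @param nStations number of stations (default 3, emulating thickness
#'   measured in three slices and averaged).
#' @param stationSpacingMm spacing between stations (default 5).
#' @param longAxis muscle long axis along which stations are spread
#'   (default +y).
#' @return Mean thickness in mm.
#' @export
thickness3d <- function(mesh, station, direction, nStations = 3L,
                        stationSpacingMm = 5, longAxis = c(0, 1, 0)) {
  dirU <- .unitv(direction)
  offs <- (seq_len(nStations) - (nStations + 1) / 2) * stationSpacingMm
  th <- vapply(offs, function(o) {
    p <- station + o * longAxis
    hSup <- rayMeshFirstHit(mesh, p, dirU)
    hDeep <- rayMeshFirstHit(mesh, p, -dirU)
    if (is.null(hSup) || is.null(hDeep))
      stop(sprintf("thickness ray missed the surface at station offset %+.1f mm",
                   o))
    hSup$t + hDeep$t
  }, numeric(1))
  mean(th)
}

#' Consistency of a tract bundle
#'
#' Mean pairwise acute angle between the tracts' end-to-end directions.
#' Bundles whose tracts do not show a consistent pattern (mean angle above
#' the threshold) are flagged for exclusion.
#'
#' @param bundle a [TractBundle-class] with at least two tracts.
#' @param thresholdDeg consistency threshold (default 20).
#' @return A [BundleQuality-class].
#' @export
bundleConsistency <- function(bundle, thresholdDeg = 20) {
  n <- nTracts(bundle)
  if (n < 2L) stop("bundle consistency needs at least two tracts")
  dirs <- t(vapply(bundle@tracts, function(t)
    .unitv(t[nrow(t), ] - t[1L, ]), numeric(3)))
  ct <- abs(tcrossprod(dirs))
  ang <- .rad2deg(acos(.clamp(ct[upper.tri(ct)], 0, 1)))
  m <- mean(ang)
  new("BundleQuality", meanPairwiseAngleDeg = m,
      consistent = m <= thresholdDeg, thresholdDeg = thresholdDeg)
}

#' DTI architecture measurement from tract bundles and the muscle mesh
#'
#' For each bundle: checks consistency, reduces the bundle to its median
#' endpoints, extends them to the muscle surface, and measures fascicle
#' length (Euclidean distance between the surface endpoints) and the deep
#' and superficial pennation angles of the median-line direction against
#' the local surface normals. Inconsistent or empty bundles are excluded
#' and logged. FL and the two pennation angles are averaged over the
#' included bundles (typically three seed regions); muscle thickness is
#' measured by [thickness3d()] at the mean mid-fascicle site. If every
#' bundle is excluded, an excluded-muscle result is returned instead of an
#' error.
#'
#' @param bundles a [TractBundle-class] or list of them (typically 3).
#' @param mesh the muscle [SurfaceMesh-class].
#' @param depthAxis deep-to-superficial axis (default +z).
#' @param longAxis muscle long axis (default +y).
#' @param radiusMm normal-averaging radius around each endpoint (default
#'   5).
#' @param thresholdDeg bundle-consistency threshold (default 20).
#' @param nStations,stationSpacingMm thickness stations (defaults 3 and 5).
#' @param muscle muscle tag for the result.
#' @param areaWeighted,complement passed to [pennationFromNormals()].
#' @return A list of class `dtiMeasurement` with elements `result` (an
#'   [ArchitectureResult-class]), `perBundle` (a data.frame of per-bundle
#'   FL/PA values and quality), and `exclusions` (character log of
#'   excluded bundles).
#' @export
measureDti <- function(bundles, mesh, depthAxis = c(0, 0, 1),
                       longAxis = c(0, 1, 0), radiusMm = 5,
                       thresholdDeg = 20, nStations = 3L,
                       stationSpacingMm = 5, muscle = "phantom",
                       areaWeighted = TRUE, complement = TRUE) {
  if (is(bundles, "TractBundle")) bundles <- list(bundles)
  stopifnot(length(bundles) >= 1L)
  per <- list(); exclusions <- character(0)
  mids <- list()
  for (b in seq_along(bundles)) {
    bun <- bundles[[b]]
    if (nTracts(bun) < 2L) {
      exclusions <- c(exclusions,
                      sprintf("bundle %d: empty or too few tracts", b))
      per[[b]] <- data.frame(bundle = b, FL_mm = NA, PA_deep_deg = NA,
                             PA_sup_deg = NA, meanPairwiseAngleDeg = NA,
                             included = FALSE)
      next
    }
    q <- bundleConsistency(bun, thresholdDeg)
    if (!q@consistent) {
      exclusions <- c(exclusions, sprintf(
        "bundle %d: inconsistent tract pattern (mean pairwise angle %.1f deg > %.1f)",
        b, q@meanPairwiseAngleDeg, thresholdDeg))
      per[[b]] <- data.frame(bundle = b, FL_mm = NA, PA_deep_deg = NA,
                             PA_sup_deg = NA,
                             meanPairwiseAngleDeg = q@meanPairwiseAngleDeg,
                             included = FALSE)
      next
    }
    me <- medianEndpoints(bun, depthAxis)
    ext <- extendToSurface(me$deep, me$sup, mesh)
    fl <- fascicleLength(ext$deep, ext$sup)
    tdir <- .unitv(ext$sup - ext$deep)
    paD <- pennationFromNormals(tdir, mesh, ext$deep, radiusMm,
                                areaWeighted, complement)
    paS <- pennationFromNormals(tdir, mesh, ext$sup, radiusMm,
                                areaWeighted, complement)
    mids[[length(mids) + 1L]] <- (ext$deep + ext$sup) / 2
    per[[b]] <- data.frame(bundle = b, FL_mm = fl, PA_deep_deg = paD,
                           PA_sup_deg = paS,
                           meanPairwiseAngleDeg = q@meanPairwiseAngleDeg,
                           included = TRUE)
  }
  perBundle <- do.call(rbind, per)
  inc <- perBundle$included
  if (!any(inc)) {
    res <- architectureResult(NA, NA, NA, NA, method = "DTI",
                              muscle = muscle, excluded = TRUE)
  } else {
    site <- colMeans(do.call(rbind, mids))
    tm <- thickness3d(mesh, site, depthAxis, nStations, stationSpacingMm,
                      longAxis)
    res <- architectureResult(
      flMm = mean(perBundle$FL_mm[inc]),
      paDeepDeg = mean(perBundle$PA_deep_deg[inc]),
      paSupDeg = mean(perBundle$PA_sup_deg[inc]),
      tmMm = tm, method = "DTI", muscle = muscle)
  }
  structure(list(result = res, perBundle = perBundle,
                 exclusions = exclusions),
            class = "dtiMeasurement")
}

#' @export
print.dtiMeasurement <- function(x, ...) {
  show(x$result)
  if (length(x$exclusions))
    cat("exclusions:\n", paste(" -", x$exclusions, collapse = "\n"), "\n")
  invisible(x)
}
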