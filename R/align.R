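# Rigid registration of the ultrasound/motion-capture frame to the MR
# frame from the P1-P4 marker cluster, scan-plane construction from the
# probe markers AL/AR/AU, and seeding of tractography at the plane-muscle
# intersection.

#' Least-squares rigid transform between matched point sets
#'
#' Orthogonal Procrustes (Kabsch) fit of rotation and translation mapping
#' `src` onto `dst`, with the reflection guard that forces a proper
#' rotation (det +1).
#'
#' @param src,dst matched n x 3 matrices (n >= 3, not collinear), world mm.
#' @return A [RigidTransform-class] with `rmsResidual` filled in.
#' @export
fitRigidTransform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || !all(dim(src) == dim(dst)))
    stop("need at least 3 matched points in both frames")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2L, cs); B <- sweep(dst, 2L, cd)
  sv <- svd(crossprod(A, B))
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("marker cluster is collinear or degenerate; cannot fit a rotation")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cd - drop(R %*% cs)
  res <- src %*% t(R) + matrix(tr, nrow(src), 3L, byrow = TRUE) - dst
  rigidTransform(R, tr, sqrt(mean(rowSums(res^2))))
}

#' Scan plane from the three probe markers
#'
#' AL and AR span the acquisition window of the linear transducer (their
#' distance is the window width); AU sits on the probe body away from the
#' skin. The plane passes through all three markers; the lateral axis runs
#' AL to AR, the depth axis is in-plane perpendicular to it, oriented away
#' from AU (into the body).
#'
#' @param AL,AR,AU world-mm probe marker positions (not collinear).
#' @param fovDepth imaging depth of the field of view (default 40 mm).
#' @return A [ScanPlane-class].
#' @export
scanPlaneFromProbe <- function(AL, AR, AU, fovDepth = 40) {
  lat <- AR - AL
  if (.vnorm(lat) < 1e-9) stop("AL and AR coincide")
  lat <- .unitv(lat)
  v <- AU - AL
  nrm <- .cross3(lat, v)
  if (.vnorm(nrm) < 1e-9 * .vnorm(v))
    stop("probe markers are collinear; no unique scan plane")
  nrm <- .unitv(nrm)
  dep <- .cross3(nrm, lat)
  origin <- (AL + AR) / 2
  if (sum(dep * (AU - origin)) > 0) {
    dep <- -dep
    nrm <- -nrm   # keep lateral x depth = normal right-handed
  }
  new("ScanPlane", origin = origin, normal = .cross3(lat, dep),
      lateral = lat, depth = dep, fovWidth = .vnorm(AR - AL),
      fovDepth = fovDepth)
}

.sceneCoords <- function(scene, labels, frame) {
  m <- scene@markers
  out <- matrix(NA_real_, length(labels), 3L,
                dimnames = list(labels, NULL))
  for (i in seq_along(labels)) {
    row <- m[m$label == labels[i] & m$frame == frame, , drop = FALSE]
    if (nrow(row) == 1L)
      out[i, ] <- c(row$x_mm, row$y_mm, row$z_mm)
  }
  out
}

#' Rigid US-to-MR transform fitted on the P1-P4 cluster
#'
#' @param scene a [MarkerScene-class] containing P1-P4 in both frames.
#' @return A [RigidTransform-class].
#' @export
markerTransform <- function(scene) {
  stopifnot(is(scene, "MarkerScene"))
  lab <- c("P1", "P2", "P3", "P4")
  us <- .sceneCoords(scene, lab, "US")
  mr <- .sceneCoords(scene, lab, "MR")
  miss <- lab[!stats::complete.cases(us) | !stats::complete.cases(mr)]
  if (length(miss))
    stop("missing marker(s) for the rigid fit: ", paste(miss, collapse = ", "))
  fitRigidTransform(us, mr)
}

#' Locate the ultrasound scan plane in the MR frame
#'
#' Fits the rigid US-to-MR transform on the P1-P4 cluster only, applies it
#' to the probe markers AL/AR/AU observed in the US frame, and constructs
#' the scan plane in MR coordinates.
#'
#' @param scene a [MarkerScene-class] with P1-P4 in both frames and
#'   AL/AR/AU in the US frame.
#' @param fovDepth field-of-view depth passed to [scanPlaneFromProbe()].
#' @return A [ScanPlane-class] in the MR frame.
#' @export
locateUsPlaneInMr <- function(scene, fovDepth = 40) {
  tr <- markerTransform(scene)
  probe <- .sceneCoords(scene, c("AL", "AR", "AU"), "US")
  miss <- c("AL", "AR", "AU")[!stats::complete.cases(probe)]
  if (length(miss))
    stop("missing probe marker(s) in the US frame: ",
         paste(miss, collapse = ", "))
  pm <- applyTransform(tr, probe)
  scanPlaneFromProbe(pm["AL", ], pm["AR", ], pm["AU", ], fovDepth)
}

#' Seed region(s) at the scan-plane / muscle intersection
#'
#' Intersects the scan plane with the muscle surface within the field of
#' view and places seed spheres on the polygonal cross-section: with
#' `nSites = 1`, one seed at the polygon's area centroid; with more, one
#' per equal lateral slice of the polygon, each at its slice's centroid
#' (evenly spaced along the intersection).
#'
#' @param plane a [ScanPlane-class].
#' @param mesh the muscle [SurfaceMesh-class].
#' @param radiusMm seed-sphere radius (default 2.5, one acquisition
#'   voxel).
#' @param nSites number of seed regions (default 1).
#' @return A [SeedRegion-class] (`nSites = 1`) or list of them.
#' @export
seedFromIntersection <- function(plane, mesh, radiusMm = 2.5, nSites = 1L) {
  polys <- planeMeshIntersection(plane, mesh, bounded = TRUE)
  polys <- Filter(function(p) isTRUE(attr(p, "closed")), polys)
  if (!length(polys))
    stop("no in-field-of-view intersection of the scan plane with the muscle")
  areas <- vapply(polys, function(p)
    abs(.polyArea(attr(p, "planeCoords"))), numeric(1))
  poly <- attr(polys[[which.max(areas)]], "planeCoords")
  to3d <- function(q) plane@origin + q[1L] * plane@lateral +
    q[2L] * plane@depth
  if (nSites == 1L) {
    return(seedRegion(to3d(.polyCentroid(poly)), radiusMm))
  }
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  cuts <- seq(xr[1L], xr[2L], length.out = nSites + 1L)
  out <- vector("list", nSites)
  for (i in seq_len(nSites)) {
    piece <- .clipPolyRect(poly, c(cuts[i], yr[1L] - 1, cuts[i + 1L],
                                   yr[2L] + 1))
    ctr <- if (nrow(piece) >= 3L) .polyCentroid(piece)
      else .polyCentroid(poly)
    out[[i]] <- seedRegion(to3d(ctr), radiusMm)
  }
  out
}
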