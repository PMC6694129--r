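# 2D ultrasound measurement model: architecture parameters from digitized
# aponeurosis lines and fascicle segments, and projection of phantom truth
# into a scan plane to create synthetic ultrasound observations.

.segDir2 <- function(seg) seg[2L, ] - seg[1L, ]

.foldAngle2Deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a * a) * sum(b * b))
  .rad2deg(acos(.clamp(ca, 0, 1)))
}

# perpendicular distance from point p to the infinite line through seg
.pointLineDist2 <- function(p, seg) {
  d <- .segDir2(seg)
  abs(d[1L] * (p[2L] - seg[1L, 2L]) - d[2L] * (p[1L] - seg[1L, 1L])) /
    sqrt(sum(d * d))
}

# y on the infinite line through seg at lateral position x
.lineYat <- function(seg, x) {
  d <- .segDir2(seg)
  if (abs(d[1L]) < 1e-12)
    stop("aponeurosis line is vertical in the image; cannot evaluate depth")
  seg[1L, 2L] + (x - seg[1L, 1L]) / d[1L] * d[2L]
}

#' Ultrasound-style architecture measurement from a 2D scene
#'
#' Per fascicle: the deep and superficial pennation angles are the acute
#' angles between the fascicle segment and the respective aponeurosis
#' line; muscle thickness is the distance between the aponeurosis lines
#' evaluated at the fascicle midpoint's lateral position (perpendicular to
#' the deep aponeurosis by default, or vertically in the image); fascicle
#' length is t_m divided by the sine of the deep pennation angle. The up
#' to three per-fascicle values are averaged, and the reported PA is the
#' mean of the averaged deep and superficial angles.
#'
#' @param scene a [UsScene2D-class].
#' @param tmMode `"perpendicular"` (default) measures t_m perpendicular to
#'   the deep aponeurosis line; `"vertical"` measures it along the image
#'   depth axis.
#' @param muscle muscle tag for the result.
#' @return An [ArchitectureResult-class] with method "US".
#' @examples
#' sc <- usScene2D(apoDeep = rbind(c(0, 10), c(40, 10)),
#'                 apoSup = rbind(c(0, 0), c(40, 0)),
#'                 fascicles = rbind(c(0, 10), c(10 / tan(pi / 6), 0)))
#' usMeasure(sc)  # PA 30 deg, t_m 10 mm, FL 20 mm
#' @export
usMeasure <- function(scene, tmMode = c("perpendicular", "vertical"),
                      muscle = "phantom") {
  stopifnot(is(scene, "UsScene2D"))
  validObject(scene)
  tmMode <- match.arg(tmMode)
  dDeep <- .segDir2(scene@apoDeep)
  dSup <- .segDir2(scene@apoSup)
  vals <- vapply(scene@fascicles, function(f) {
    dF <- .segDir2(f)
    paD <- .foldAngle2Deg(dF, dDeep)
    paS <- .foldAngle2Deg(dF, dSup)
    if (paD < 1e-9)
      stop("fascicle is parallel to the deep aponeurosis; FL is undefined")
    mid <- colMeans(f)
    tm <- if (tmMode == "perpendicular") {
      pd <- c(mid[1L], .lineYat(scene@apoDeep, mid[1L]))
      .pointLineDist2(pd, scene@apoSup)
    } else {
      abs(.lineYat(scene@apoDeep, mid[1L]) - .lineYat(scene@apoSup, mid[1L]))
    }
    c(paD, paS, tm, tm / sin(.deg2rad(paD)))
  }, numeric(4))
  architectureResult(flMm = mean(vals[4L, ]), paDeepDeg = mean(vals[1L, ]),
                     paSupDeg = mean(vals[2L, ]), tmMm = mean(vals[3L, ]),
                     method = "US", muscle = muscle)
}

# 2D line (point + unit direction, in scan-plane lateral/depth coords) of
# the world plane z = zLevel intersected with the scan plane
.planeLevelLine2d <- function(plane, zLevel) {
  lz <- plane@lateral[3L]; dz <- plane@depth[3L]
  if (sqrt(lz^2 + dz^2) < 1e-9)
    stop("scan plane is parallel to the aponeurosis planes")
  rhs <- zLevel - plane@origin[3L]
  p0 <- if (abs(dz) >= abs(lz)) c(0, rhs / dz) else c(rhs / lz, 0)
  list(point = p0, dir = .unitv(c(-dz, lz)))
}

.lineLineIntersect2 <- function(p0, d0, p1, d1) {
  A <- cbind(d0, -d1)
  if (abs(det(A)) < 1e-12) stop("lines are parallel")
  s <- solve(A, p1 - p0)
  p0 + s[1L] * d0
}

#' Project a phantom into a scan plane as a synthetic ultrasound scene
#'
#' Intersects the phantom's aponeurosis planes with the scan plane to give
#' the 2D aponeurosis lines, places `nFascicles` fascicle lines through
#' evenly spaced in-slab points at mid-depth, each along the orthogonal
#' projection of the 3D fascicle direction into the plane, and expresses
#' everything in scan-plane (lateral, depth) mm coordinates. This is the
#' synthetic analogue of an acquired, manually digitized B-mode image:
#' with the scan plane containing the fascicle direction the measurement
#' is exact, and yawing the plane inflates the apparent pennation angle as
#' tan(PA') = tan(PA) / cos(yaw).
#'
#' @param phantom a [Phantom-class].
#' @param plane a [ScanPlane-class] that intersects the slab.
#' @param nFascicles number of fascicle segments (default 3).
#' @return A [UsScene2D-class].
#' @export
projectPhantomToPlane <- function(phantom, plane, nFascicles = 3L) {
  stopifnot(is(phantom, "Phantom"), is(plane, "ScanPlane"))
  spec <- phantom@spec
  t <- spec@thicknessMm
  lnDeep <- .planeLevelLine2d(plane, 0)
  lnSup <- .planeLevelLine2d(plane, t)
  lnMid <- .planeLevelLine2d(plane, t / 2)
  to3d <- function(q) plane@origin + q[1L] * plane@lateral +
    q[2L] * plane@depth
  # in-slab span of the mid-depth line
  uu <- seq(-300, 300, by = 0.5)
  ptsW <- t(vapply(uu, function(u) to3d(lnMid$point + u * lnMid$dir),
                   numeric(3)))
  insl <- abs(ptsW[, 1L]) <= spec@widthMm / 2 & ptsW[, 2L] >= 0 &
    ptsW[, 2L] <= spec@muscleLengthMm
  if (!any(insl))
    stop("scan plane does not intersect the phantom slab")
  uin <- range(uu[insl])
  d <- phantom@fascicleDirection
  f2 <- c(sum(d * plane@lateral), sum(d * plane@depth))
  if (.vnorm(f2) < 1e-9)
    stop("fascicle direction is perpendicular to the scan plane")
  f2 <- .unitv(f2)
  frac <- (seq_len(nFascicles)) / (nFascicles + 1)
  fas <- lapply(frac, function(fr) {
    base <- lnMid$point + (uin[1L] + fr * diff(uin)) * lnMid$dir
    pD <- .lineLineIntersect2(base, f2, lnDeep$point, lnDeep$dir)
    pS <- .lineLineIntersect2(base, f2, lnSup$point, lnSup$dir)
    rbind(pD, pS)
  })
  lat <- unlist(lapply(fas, function(f) f[, 1L]))
  span <- range(lat) + c(-5, 5)
  segOn <- function(ln) rbind(
    ln$point + ((span[1L] - ln$point[1L]) / ln$dir[1L]) * ln$dir,
    ln$point + ((span[2L] - ln$point[1L]) / ln$dir[1L]) * ln$dir)
  # guard nearly-vertical aponeurosis lines in image coords
  if (abs(lnDeep$dir[1L]) < 1e-9)
    stop("aponeurosis line is perpendicular to the image lateral axis")
  usScene2D(apoDeep = segOn(lnDeep), apoSup = segOn(lnSup), fascicles = fas)
}
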