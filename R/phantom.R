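# Synthetic unipennate muscle phantoms with analytic ground truth.
#
# The phantom idealizes a unipennate compartment (gastrocnemius-like) as
# the slab between two parallel aponeurosis planes, clipped to a box.
# World frame: right-handed, mm, line of action along +y, depth along +z,
# deep aponeurosis at smaller z. This makes FL, PA and t_m analytic, so
# recovery tests have exact oracles: FL = t_m / sin(PA).

#' Construct a phantom specification
#'
#' @param thicknessMm distance between the aponeurosis planes (mm); must be
#'   smaller than `muscleLengthMm`.
#' @param pennationDeg fascicle angle to the aponeuroses, in (0, 90\].
#' @param muscleLengthMm compartment extent along the line of action
#'   (default 60).
#' @param widthMm medio-lateral extent (default 40).
#' @param voxelSizeMm isotropic voxel size (default 2.5, the DTI
#'   acquisition resolution emulated here).
#' @param faInside,faOutside fractional anisotropy inside/outside the
#'   muscle (defaults 0.35 / 0.05).
#' @param endpointJitterSdMm Gaussian endpoint noise for synthetic tracts
#'   (default 0).
#' @param truncationMm gap between synthetic tract ends and the
#'   aponeuroses, along the tract line (default 0).
#' @param nTracts tracts per synthetic bundle (default 100).
#' @param rngSeed seed for phantom randomness (default 1).
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(thicknessMm = 10, pennationDeg = 30)
#' groundTruth(makeUnipennatePhantom(spec))  # FL = 20 mm
#' @export
phantomSpec <- function(thicknessMm, pennationDeg, muscleLengthMm = 60,
                        widthMm = 40, voxelSizeMm = 2.5, faInside = 0.35,
                        faOutside = 0.05, endpointJitterSdMm = 0,
                        truncationMm = 0, nTracts = 100L, rngSeed = 1L) {
  new("PhantomSpec", thicknessMm = thicknessMm, pennationDeg = pennationDeg,
      muscleLengthMm = muscleLengthMm, widthMm = widthMm,
      voxelSizeMm = voxelSizeMm, faInside = faInside, faOutside = faOutside,
      endpointJitterSdMm = endpointJitterSdMm, truncationMm = truncationMm,
      nTracts = as.integer(nTracts), rngSeed = as.integer(rngSeed))
}

# Eigenvalues (lambda1, lambda2 = lambda3) of a prolate tensor with given
# FA and mean diffusivity. For (a, b, b): FA = (a - b) / sqrt(a^2 + 2 b^2).
.prolateEigenvalues <- function(fa, md = 1.5e-3) {
  if (fa <= 0) return(c(md, md, md))
  f <- function(r) (r - 1) / sqrt(r^2 + 2) - fa
  r <- uniroot(f, c(1 + 1e-9, 1e6), tol = 1e-14)$root
  b <- 3 * md / (r + 2)
  c(r * b, b, b)
}

.tensorFromFrame <- function(lambda, d) {
  u <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- .unitv(.cross3(d, u))
  e3 <- .cross3(d, e2)
  D <- lambda[1L] * tcrossprod(d) + lambda[2L] * tcrossprod(e2) +
    lambda[3L] * tcrossprod(e3)
  (D + t(D)) / 2
}

#' Generate a unipennate slab phantom
#'
#' Builds the voxelized label map (1 inside the slab compartment, 0
#' outside), the diffusion-tensor field (principal eigenvector along the
#' fascicle direction with FA `faInside` inside; low-FA tensors along +x
#' outside), the analytic aponeurosis planes and the exact ground-truth
#' architecture. The grid is padded by three voxels on every side and
#' voxel centers are offset half a voxel from the aponeurosis planes, so
#' integer-multiple thicknesses digitize without bias.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [Phantom-class].
#' @export
makeUnipennatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@voxelSizeMm
  t <- spec@thicknessMm; L <- spec@muscleLengthMm; w <- spec@widthMm
  theta <- .deg2rad(spec@pennationDeg)
  pad <- 3L
  nx <- as.integer(ceiling(w / h)) + 2L * pad
  ny <- as.integer(ceiling(L / h)) + 2L * pad
  nz <- as.integer(ceiling(t / h)) + 2L * pad
  # voxel centers: x symmetric about 0; y, z start half a voxel past the
  # slab faces at y = 0 and z = 0
  x0 <- -(nx - 1L) / 2 * h
  y0 <- -pad * h + h / 2
  z0 <- -pad * h + h / 2
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4L] <- c(x0, y0, z0)

  xc <- x0 + (seq_len(nx) - 1L) * h
  yc <- y0 + (seq_len(ny) - 1L) * h
  zc <- z0 + (seq_len(nz) - 1L) * h
  inside <- outer(outer(abs(xc) <= w / 2, yc >= 0 & yc <= L, "&"),
                  zc > 0 & zc < t, "&")
  labels <- array(as.integer(inside), c(nx, ny, nz))

  d <- c(0, cos(theta), sin(theta))
  Din <- .tensorFromFrame(.prolateEigenvalues(spec@faInside), d)
  Dout <- .tensorFromFrame(.prolateEigenvalues(spec@faOutside), c(1, 0, 0))
  comp <- function(D) c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
  ci <- comp(Din); co <- comp(Dout)
  tensors <- array(0, c(nx, ny, nz, 6L))
  for (m in 1:6)
    tensors[, , , m] <- ifelse(inside, ci[m], co[m])

  truth <- architectureResult(flMm = t / sin(theta),
                              paDeepDeg = spec@pennationDeg,
                              paSupDeg = spec@pennationDeg, tmMm = t,
                              method = "truth", muscle = "phantom")
  new("Phantom", labels = labels, affine = affine,
      tensorVolume = tensorVolume(tensors, affine),
      deepPlane = list(point = c(0, 0, 0), normal = c(0, 0, -1)),
      supPlane = list(point = c(0, 0, t), normal = c(0, 0, 1)),
      truth = truth, fascicleDirection = d, spec = spec)
}

#' Label map of a phantom at a different voxel size
#'
#' Re-voxelizes the analytic slab geometry (not the stored label map), so
#' a fine grid for surface meshing can coexist with the coarser tensor
#' grid.
#'
#' @param phantom a [Phantom-class].
#' @param voxelSizeMm target voxel size.
#' @return List with `labels` (3D integer array) and `affine`.
#' @export
phantomLabelMap <- function(phantom, voxelSizeMm = NULL) {
  spec <- phantom@spec
  if (is.null(voxelSizeMm) || voxelSizeMm == spec@voxelSizeMm)
    return(list(labels = phantom@labels, affine = phantom@affine))
  spec2 <- phantomSpec(spec@thicknessMm, spec@pennationDeg,
                       spec@muscleLengthMm, spec@widthMm,
                       voxelSizeMm = voxelSizeMm, faInside = spec@faInside,
                       faOutside = spec@faOutside, rngSeed = spec@rngSeed)
  ph2 <- makeUnipennatePhantom(spec2)
  list(labels = ph2@labels, affine = ph2@affine)
}

#' Emulate a tractography bundle from a phantom
#'
#' Draws `spec@nTracts` straight fascicle lines along the phantom's
#' fascicle direction through a small region in the middle of the slab.
#' Each line runs from the deep to the superficial aponeurosis, receded by
#' `truncationMm` at both ends along the line (tractography stops short of
#' the boundary); its endpoints are then jittered with iid Gaussian noise
#' of sd `endpointJitterSdMm` per coordinate, and the polyline is sampled
#' at ~1 mm spacing. Deterministic for a fixed `spec@rngSeed`.
#'
#' @param phantom a [Phantom-class].
#' @param spec a [PhantomSpec-class]; defaults to the phantom's own spec.
#' @param rngSeed optional seed overriding `spec@rngSeed`.
#' @return A [TractBundle-class].
#' @export
synthesizeTracts <- function(phantom, spec = phantom@spec, rngSeed = NULL) {
  stopifnot(is(phantom, "Phantom"), is(spec, "PhantomSpec"))
  t <- spec@thicknessMm
  theta <- .deg2rad(spec@pennationDeg)
  d <- phantom@fascicleDirection
  fl <- t / sin(theta)
  n <- spec@nTracts
  runY <- t / tan(theta)   # in-plane advance of a full fascicle
  center <- c(0, (spec@muscleLengthMm - runY) / 2, 0)
  regionR <- min(spec@widthMm / 4, spec@muscleLengthMm / 8, 10)
  seed <- if (is.null(rngSeed)) spec@rngSeed else rngSeed
  pts <- .withSeed(seed, {
    ang <- runif(n, 0, 2 * pi)
    rad <- regionR * sqrt(runif(n))
    base <- cbind(center[1L] + rad * cos(ang), center[2L] + rad * sin(ang),
                  0)
    jit <- matrix(rnorm(n * 6L, sd = spec@endpointJitterSdMm), ncol = 6L)
    list(base = base, jit = jit)
  })
  tracts <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- pts$base[i, ] + spec@truncationMm * d + pts$jit[i, 1:3]
    p2 <- pts$base[i, ] + (fl - spec@truncationMm) * d + pts$jit[i, 4:6]
    len <- .vnorm(p2 - p1)
    ns <- max(2L, as.integer(ceiling(len)) + 1L)
    s <- seq(0, 1, length.out = ns)
    tracts[[i]] <- cbind(p1[1L] + s * (p2[1L] - p1[1L]),
                         p1[2L] + s * (p2[2L] - p1[2L]),
                         p1[3L] + s * (p2[3L] - p1[3L]))
  }
  tractBundle(tracts, seed = seedRegion(center + c(0, runY / 2, t / 2),
                                        regionR))
}

# Canonical MR-frame marker layout (mm): the P1-P4 cluster on a silicon
# pad over the tibia, anatomical context markers P5-P8, and the probe
# markers AL/AR/AU positioned so the scan plane looks down (-z) onto a
# slab phantom at the origin. AL-AR distance is the 38 mm transducer
# acquisition window.
.defaultMarkerLayoutMr <- function() {
  rbind(P1 = c(-40, 5, 22), P2 = c(40, 5, 22), P3 = c(40, 55, 15),
        P4 = c(-40, 55, 15), P5 = c(-45, 80, 35), P6 = c(40, 90, 30),
        P7 = c(40, -10, 25), P8 = c(-50, 40, 10),
        # probe held longitudinally over the slab: acquisition window along
        # the line of action (+y), centered mid-muscle, looking down -z
        AL = c(0, 26, 30), AR = c(0, 64, 30), AU = c(0, 45, 75))
}

#' Generate a synthetic two-frame marker scene
#'
#' Places the canonical marker layout (P1-P8 on the leg, AL/AR/AU on the
#' probe) in the MR frame, derives the ultrasound-frame coordinates through
#' the inverse of `trueTransform` (so that MR = transform(US) exactly
#' before noise), then perturbs each marker independently in each frame
#' with iid Gaussian noise.
#'
#' @param trueTransform the ground-truth [RigidTransform-class] mapping the
#'   US frame to the MR frame.
#' @param noiseSdMm per-coordinate Gaussian noise sd (default 0).
#' @param rngSeed seed for the noise draw.
#' @param layoutMr optional 11 x 3 matrix (rownames P1..P8, AL, AR, AU)
#'   overriding the canonical MR-frame layout.
#' @return A [MarkerScene-class] with `trueTransform` retained.
#' @export
makeMarkerScene <- function(trueTransform = rigidTransform(),
                            noiseSdMm = 0, rngSeed = 1L,
                            layoutMr = .defaultMarkerLayoutMr()) {
  stopifnot(is(trueTransform, "RigidTransform"))
  validObject(trueTransform)
  mr <- as.matrix(layoutMr)
  us <- applyTransform(invertTransform(trueTransform), mr)
  noise <- .withSeed(rngSeed,
    matrix(rnorm(2L * length(mr), sd = noiseSdMm), ncol = 3L))
  nm <- nrow(mr)
  usObs <- us + noise[seq_len(nm), , drop = FALSE]
  mrObs <- mr + noise[nm + seq_len(nm), , drop = FALSE]
  markers <- rbind(
    data.frame(label = rownames(mr), frame = "US", x_mm = usObs[, 1L],
               y_mm = usObs[, 2L], z_mm = usObs[, 3L],
               stringsAsFactors = FALSE),
    data.frame(label = rownames(mr), frame = "MR", x_mm = mrObs[, 1L],
               y_mm = mrObs[, 2L], z_mm = mrObs[, 3L],
               stringsAsFactors = FALSE))
  rownames(markers) <- NULL
  new("MarkerScene", markers = markers, trueTransform = trueTransform)
}
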