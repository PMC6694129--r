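# Deterministic streamline tractography on a diffusion-tensor volume,
# emulating DSI-Studio-style muscle fibre tracking: fixed-step Euler
# integration along the principal eigenvector with FA-window, curvature
# and length stopping rules.

#' Fractional anisotropy of a diffusion tensor
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, computed from
#' the tensor's Frobenius invariants (no eigendecomposition needed). The
#' all-zero tensor has FA 0 by definition; tiny negative eigenvalues from
#' noise are harmless since only quadratic invariants enter.
#'
#' @param tensor symmetric 3x3 matrix (mm^2/s).
#' @return FA in \[0, 1\].
#' @examples
#' fractionalAnisotropy(diag(c(1, 1, 1) * 1e-3))  # 0, isotropic
#' fractionalAnisotropy(diag(c(1, 0, 0)))         # 1, stick
#' @export
fractionalAnisotropy <- function(tensor) {
  if (max(abs(tensor)) == 0) return(0)
  if (max(abs(tensor - t(tensor))) > 1e-9 * max(abs(tensor)))
    stop("tensor must be symmetric")
  tr <- sum(diag(tensor))
  dev <- tensor - diag(tr / 3, 3L)
  fa <- sqrt(1.5 * sum(dev * dev) / sum(tensor * tensor))
  min(max(fa, 0), 1)
}

#' Per-voxel FA map of a tensor volume
#'
#' Vectorized over the whole grid using the same invariant formula as
#' [fractionalAnisotropy()].
#'
#' @param vol a [TensorVolume-class].
#' @return 3D numeric array of FA values.
#' @export
faVolume <- function(vol) {
  tx <- vol@tensors
  # components: 1 Dxx, 2 Dxy, 3 Dyy, 4 Dxz, 5 Dyz, 6 Dzz
  dxx <- tx[, , , 1L]; dxy <- tx[, , , 2L]; dyy <- tx[, , , 3L]
  dxz <- tx[, , , 4L]; dyz <- tx[, , , 5L]; dzz <- tx[, , , 6L]
  frob2 <- dxx^2 + dyy^2 + dzz^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  tr <- dxx + dyy + dzz
  dev2 <- frob2 - tr^2 / 3
  fa <- sqrt(1.5 * pmax(dev2, 0) / pmax(frob2, .Machine$double.xmin))
  fa[frob2 == 0] <- 0
  array(pmin(fa, 1), dim(dxx))
}

#' Construct tracking parameters
#'
#' @param faMin,faMax FA window; tracking stops outside it. Defaults 0.1
#'   and 0.7.
#' @param maxTurnDeg maximum angle between consecutive segments (default
#'   10).
#' @param minLenMm,maxLenMm retained arc-length window (defaults 20 and
#'   200).
#' @param stepMm Euler step (default 1.0).
#' @param nTracts seeds per region (default 100).
#' @return A [TrackingParams-class].
#' @export
trackingParams <- function(faMin = 0.1, faMax = 0.7, maxTurnDeg = 10,
                           minLenMm = 20, maxLenMm = 200, stepMm = 1.0,
                           nTracts = 100L) {
  new("TrackingParams", faMin = faMin, faMax = faMax,
      maxTurnDeg = maxTurnDeg, minLenMm = minLenMm, maxLenMm = maxLenMm,
      stepMm = stepMm, nTracts = as.integer(nTracts))
}

# principal eigenvector of the tensor at a 1-based voxel index, memoized
.eigvecCache <- function(vol) {
  cache <- new.env(parent = emptyenv())
  dims <- vol@dims
  function(i, j, k) {
    key <- as.character((i - 1L) + dims[1L] * ((j - 1L) + dims[2L] * (k - 1L)))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    D <- tensorAt(vol, i, j, k)
    e <- eigen(D, symmetric = TRUE)
    v <- e$vectors[, 1L]
    cache[[key]] <- v
    v
  }
}

# world mm -> nearest 1-based voxel index, NULL if outside the grid
.nearestVoxel <- function(invAffine, dims, p) {
  v <- invAffine %*% c(p, 1)
  ijk <- round(v[1:3]) + 1L
  if (any(ijk < 1L) || any(ijk > dims)) return(NULL)
  ijk
}

#' Deterministic streamline tracking
#'
#' Draws `params@nTracts` seed points uniformly in the seed sphere
#' (seeded RNG) and integrates each in both directions with fixed-step
#' Euler along the principal eigenvector of the nearest voxel's tensor
#' (piecewise-constant interpolation). The eigenvector sign is aligned
#' with the previous step; the first step is aligned with `refAxis`. A
#' step terminates its tract when the local FA leaves
#' `[faMin, faMax]`, the turn from the previous segment exceeds
#' `maxTurnDeg`, or the point exits the volume. Tracts whose total
#' polyline arc length falls outside `[minLenMm, maxLenMm]` are
#' discarded. If every tract is discarded an empty bundle is returned
#' with its `emptyWarning` flag set (the muscle is then excluded rather
#' than the analysis aborted).
#'
#' @param vol a [TensorVolume-class].
#' @param seeds a [SeedRegion-class]; the center must lie inside the
#'   volume.
#' @param params a [TrackingParams-class].
#' @param rngSeed integer seed for the seed-point draw.
#' @param refAxis direction used to orient the very first step (default
#'   +y, the phantom line of action).
#' @return A [TractBundle-class].
#' @export
trackStreamlines <- function(vol, seeds, params = trackingParams(),
                             rngSeed = 1L, refAxis = c(0, 1, 0)) {
  stopifnot(is(vol, "TensorVolume"), is(seeds, "SeedRegion"),
            is(params, "TrackingParams"))
  invAff <- solve(vol@affine)
  if (is.null(.nearestVoxel(invAff, vol@dims, seeds@center)))
    stop("seed center lies outside the volume")
  fa <- faVolume(vol)
  eigAt <- .eigvecCache(vol)
  step <- params@stepMm
  maxSteps <- ceiling(params@maxLenMm / step) + 2L
  cosMax <- cos(.deg2rad(params@maxTurnDeg))

  seedPts <- .withSeed(rngSeed, {
    u <- matrix(rnorm(params@nTracts * 3L), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    r <- seeds@radius * runif(params@nTracts)^(1 / 3)
    sweep(u * r, 2L, seeds@center, "+")
  })

  faOK <- function(ijk) {
    f <- fa[ijk[1L], ijk[2L], ijk[3L]]
    f >= params@faMin && f <= params@faMax
  }

  integrate1 <- function(p0, dir0) {
    pts <- vector("list", maxSteps)
    n <- 0L
    p <- p0; dir <- dir0
    repeat {
      if (n >= maxSteps) break
      pn <- p + step * dir
      ijk <- .nearestVoxel(invAff, vol@dims, pn)
      if (is.null(ijk) || !faOK(ijk)) break
      n <- n + 1L
      pts[[n]] <- pn
      e <- eigAt(ijk[1L], ijk[2L], ijk[3L])
      if (sum(e * dir) < 0) e <- -e
      if (sum(e * dir) < cosMax) break   # next segment would over-turn
      p <- pn; dir <- e
    }
    if (n == 0L) NULL else do.call(rbind, pts[seq_len(n)])
  }

  tracts <- list()
  nDiscarded <- 0L
  for (s in seq_len(params@nTracts)) {
    p0 <- seedPts[s, ]
    ijk <- .nearestVoxel(invAff, vol@dims, p0)
    if (is.null(ijk) || !faOK(ijk)) { nDiscarded <- nDiscarded + 1L; next }
    e0 <- eigAt(ijk[1L], ijk[2L], ijk[3L])
    if (sum(e0 * refAxis) < 0) e0 <- -e0
    fwd <- integrate1(p0, e0)
    bwd <- integrate1(p0, -e0)
    tract <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), ,
                                          drop = FALSE],
                   matrix(p0, 1L, 3L), fwd)
    if (nrow(tract) < 2L) { nDiscarded <- nDiscarded + 1L; next }
    len <- (nrow(tract) - 1L) * step
    if (len < params@minLenMm || len > params@maxLenMm) {
      nDiscarded <- nDiscarded + 1L
      next
    }
    tracts[[length(tracts) + 1L]] <- tract
  }
  if (!length(tracts))
    warning("tracking retained no tracts; returning an empty bundle")
  tractBundle(tracts, seed = seeds, nDiscarded = nDiscarded,
              emptyWarning = !length(tracts))
}
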