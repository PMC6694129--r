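# Step-4 architecture computations: median endpoints, surface extension,
# pennation from local normals, thickness, bundle consistency and the
# assembled DTI measurement.

test_that("median endpoints reduce a bundle component-wise", {
  tr <- cbind(c(0, 1, 2), 0, c(0, 0.5, 1))
  b <- tractBundle(list(tr, tr, tr))
  me <- medianEndpoints(b)
  expect_equal(me$deep, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(me$sup, c(2, 0, 1), tolerance = 1e-12)

  mk <- function(x0) rbind(c(x0, 0, 0), c(x0, 0, 10))
  b3 <- tractBundle(list(mk(0), mk(2), mk(4)))
  expect_equal(medianEndpoints(b3)$deep, c(2, 0, 0), tolerance = 1e-12)

  # flipped tract ordering must not change the result
  b3r <- tractBundle(list(mk(0), mk(2)[2:1, ], mk(4)))
  expect_equal(medianEndpoints(b3r)$deep, medianEndpoints(b3)$deep)

  set.seed(8)
  trs <- lapply(1:21, function(i) {
    p1 <- rnorm(3); rbind(p1, p1 + c(0.3, 0.2, 1) + rnorm(3, sd = 0.05))
  })
  br <- tractBundle(trs)
  me <- medianEndpoints(br)
  starts <- t(sapply(trs, function(t) t[1, ]))
  ends <- t(sapply(trs, function(t) t[2, ]))
  expect_equal(unname(me$deep), unname(apply(starts, 2, median)),
               tolerance = 1e-12)
  expect_equal(unname(me$sup), unname(apply(ends, 2, median)),
               tolerance = 1e-12)
  expect_error(medianEndpoints(tractBundle(list())), "empty")
})

test_that("endpoints extend to the surface along the median line", {
  slab <- openSlabMesh(0, 10)
  e1 <- c(0, 0, 2); e2 <- c(2 * sqrt(3), 0, 4)   # 30-degree line
  ext <- extendToSurface(e1, e2, slab)
  expect_equal(ext$deep, c(-2 * sqrt(3), 0, 0), tolerance = 1e-9)
  expect_equal(ext$sup, c(8 * sqrt(3), 0, 10), tolerance = 1e-9)
  expect_equal(fascicleLength(ext$deep, ext$sup), 20, tolerance = 1e-9)

  onSurf <- extendToSurface(c(0, 0, 0), c(2 * sqrt(3), 0, 10) * 0.999 +
                              c(0, 0, 0.01), slab)
  expect_equal(onSurf$deep, c(0, 0, 0), tolerance = 1e-6)

  expect_error(extendToSurface(c(0, 0, 5), c(5, 0, 5), slab),
               "does not intersect")
  expect_error(extendToSurface(c(0, 0, 5), c(0, 0, 5), slab), "coincide")
})

test_that("pennation against local normals matches planar trigonometry", {
  slab <- openSlabMesh(0, 10, half = 50)
  d30 <- c(0, cos(pi / 6), sin(pi / 6))
  expect_equal(pennationFromNormals(d30, slab, c(0, 0, 10)), 30,
               tolerance = 1e-9)
  expect_equal(pennationFromNormals(c(0, 1, 0), slab, c(0, 0, 10)), 0,
               tolerance = 1e-9)
  expect_equal(pennationFromNormals(c(0, 0, 1), slab, c(0, 0, 10)), 90,
               tolerance = 1e-9)
  # complement switch reports the raw angle to the normal
  expect_equal(pennationFromNormals(d30, slab, c(0, 0, 10),
                                    complement = FALSE), 60,
               tolerance = 1e-9)
})

test_that("pennation on a curved patch equals the brute-force average", {
  sph <- icosphereMesh(100, 4)
  pole <- c(0, 0, 100)
  d <- c(cos(pi / 6), 0, sin(pi / 6))   # 30 deg to the pole tangent plane
  mine <- pennationFromNormals(d, sph, pole, radiusMm = 5)
  ctr <- (sph@vertices[sph@triangles[, 1], ] +
            sph@vertices[sph@triangles[, 2], ] +
            sph@vertices[sph@triangles[, 3], ]) / 3
  sel <- rowSums(sweep(ctr, 2, pole)^2) <= 25
  ar <- muscleArch:::.triangleAreas(sph@vertices, sph@triangles)[sel]
  ang <- 90 - acos(abs(drop(sph@normals[sel, ] %*% d))) * 180 / pi
  expect_equal(mine, sum(ar * ang) / sum(ar), tolerance = 1e-9)
  expect_equal(mine, 30, tolerance = 0.5)
})

test_that("thickness is averaged over stations along the long axis", {
  slab <- openSlabMesh(0, 10)
  expect_equal(thickness3d(slab, c(0, 0, 5), c(0, 0, 1)), 10,
               tolerance = 1e-9)
  expect_equal(thickness3d(slab, c(13, -7, 2), c(0, 0, 1)), 10,
               tolerance = 1e-9)
  wedge <- wedgeMesh(slope = 0.2)
  expect_equal(thickness3d(wedge, c(0, 0, 5), c(0, 0, 1), nStations = 3,
                           stationSpacingMm = 5), 10, tolerance = 1e-9)
  expect_error(thickness3d(slab, c(0, 0, 5), c(0, 1, 0)), "missed")
})

test_that("bundle consistency measures mean pairwise direction spread", {
  mk <- function(d) rbind(c(0, 0, 0), d)
  par <- tractBundle(lapply(1:6, function(i) mk(c(0, 1, 1))))
  q <- bundleConsistency(par)
  expect_lt(q@meanPairwiseAngleDeg, 1e-3)   # acos precision floor near 0
  expect_true(q@consistent)

  orth <- tractBundle(c(lapply(1:4, function(i) mk(c(1, 0, 0))),
                        lapply(1:4, function(i) mk(c(0, 1, 0)))))
  qo <- bundleConsistency(orth)
  # 16 of 28 pairs at 90 degrees
  expect_equal(qo@meanPairwiseAngleDeg, 90 * 16 / 28, tolerance = 1e-9)
  expect_false(qo@consistent)

  set.seed(31)
  dirs <- matrix(rnorm(45), ncol = 3)
  iso <- tractBundle(lapply(seq_len(nrow(dirs)), function(i)
    mk(dirs[i, ] / sqrt(sum(dirs[i, ]^2)))))
  qi <- bundleConsistency(iso)
  ang <- c()
  for (i in 1:14) for (j in (i + 1):15) {
    a <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    b <- dirs[j, ] / sqrt(sum(dirs[j, ]^2))
    ang <- c(ang, acos(min(abs(sum(a * b)), 1)) * 180 / pi)
  }
  expect_equal(qi@meanPairwiseAngleDeg, mean(ang), tolerance = 1e-9)
  expect_error(bundleConsistency(tractBundle(list(mk(c(1, 0, 0))))),
               "two tracts")
})

test_that("measureDti recovers phantom truth from noiseless bundles", {
  # gastrocnemius-like medians; the mesh grid (0.5 mm) keeps the
  # digitization of the non-integer 11.6 mm thickness below the assertion
  spec <- phantomSpec(11.6, 29.3, muscleLengthMm = 45, widthMm = 30,
                      voxelSizeMm = 2.5)
  ph <- makeUnipennatePhantom(spec)
  lm <- phantomLabelMap(ph, 0.5)
  mesh <- meshFromLabelMap(lm$labels, lm$affine)
  out <- measureDti(phantomBundles(ph), mesh)
  tr <- groundTruth(ph)
  expect_false(out$result@excluded)
  expect_lt(abs(out$result@flMm - tr@flMm), 0.5)
  expect_lt(abs(out$result@paDeg - tr@paDeg), 1)
  expect_lt(abs(out$result@tmMm - tr@tmMm), 0.2)
  expect_equal(out$result@flMm, 23.70, tolerance = 0.5)
})

test_that("inconsistent bundles are excluded and logged", {
  spec <- phantomSpec(10, 30, voxelSizeMm = 2.5, nTracts = 30L)
  ph <- makeUnipennatePhantom(spec)
  lm <- phantomLabelMap(ph, 1)
  mesh <- meshFromLabelMap(lm$labels, lm$affine)
  good <- phantomBundles(ph, seeds = 1:2)
  # scatter the third bundle isotropically
  set.seed(77)
  bad <- tractBundle(lapply(1:30, function(i) {
    d <- rnorm(3); d <- 8 * d / sqrt(sum(d^2))
    p <- c(runif(1, -5, 5), runif(1, 20, 40), 5)
    rbind(p - d / 2, p + d / 2)
  }))
  out <- measureDti(c(good, list(bad)), mesh)
  expect_false(out$result@excluded)
  expect_equal(sum(out$perBundle$included), 2)
  expect_match(out$exclusions, "inconsistent", all = TRUE)
  expect_lt(abs(out$result@flMm - 20), 0.5)

  allBad <- measureDti(list(bad, bad, bad), mesh)
  expect_true(allBad$result@excluded)
  expect_true(is.na(allBad$result@flMm))
})

test_that("measureDti is invariant to tract order and rigid motion", {
  spec <- phantomSpec(12, 30, voxelSizeMm = 2.5, nTracts = 40L)
  ph <- makeUnipennatePhantom(spec)
  lm <- phantomLabelMap(ph, 1)
  mesh <- meshFromLabelMap(lm$labels, lm$affine)
  bundles <- phantomBundles(ph)
  out1 <- measureDti(bundles, mesh)

  # order invariance, including under endpoint noise
  specJ <- spec; specJ@endpointJitterSdMm <- 0.5
  bundlesJ <- lapply(1:3, function(i) synthesizeTracts(ph, specJ, i))
  outJ <- measureDti(bundlesJ, mesh)
  shuf <- lapply(bundlesJ, function(b) {
    set.seed(4)
    tractBundle(b@tracts[sample(nTracts(b))], b@seed)
  })
  out2 <- measureDti(shuf, mesh)
  expect_equal(outJ$result@flMm, out2$result@flMm, tolerance = 1e-9)
  expect_equal(outJ$result@paDeg, out2$result@paDeg, tolerance = 1e-9)

  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(0.3), sin(0.3), 0, -sin(0.3),
                 cos(0.3)), 3, 3)
  R <- R2 %*% R
  shift <- c(12, -5, 30)
  moveB <- lapply(bundles, function(b)
    tractBundle(lapply(b@tracts, function(t)
      t %*% t(R) + matrix(shift, nrow(t), 3, byrow = TRUE))))
  meshM <- surfaceMesh(mesh@vertices %*% t(R) +
                         matrix(shift, nrow(mesh@vertices), 3,
                                byrow = TRUE), mesh@triangles)
  outM <- measureDti(moveB, meshM, depthAxis = drop(R %*% c(0, 0, 1)),
                     longAxis = drop(R %*% c(0, 1, 0)))
  expect_equal(outM$result@flMm, out1$result@flMm, tolerance = 1e-6)
  expect_equal(outM$result@paDeg, out1$result@paDeg, tolerance = 1e-6)
  expect_equal(outM$result@tmMm, out1$result@tmMm, tolerance = 1e-6)
})
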