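# Rigid registration, scan-plane construction and intersection seeding.

test_that("rigid fits invert generated transforms exactly at zero noise", {
  sc0 <- makeMarkerScene(rigidTransform())
  fit0 <- markerTransform(sc0)
  expect_lt(max(abs(fit0@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fit0@translation)), 1e-9)
  expect_lt(fit0@rmsResidual, 1e-9)

  set.seed(13)
  for (i in 1:10) {
    ax <- rnorm(3); ang <- runif(1, 5, 170)
    R <- muscleArch:::.axisAngleRotation(ax, ang)
    tr <- rigidTransform(R, rnorm(3, sd = 50))
    fit <- markerTransform(makeMarkerScene(tr))
    expect_lt(max(abs(fit@rotation - tr@rotation)), 1e-9)
    expect_lt(max(abs(fit@translation - tr@translation)), 1e-8)
    expect_lt(fit@rmsResidual, 1e-9)
  }
})

test_that("noisy marker fits agree with the quaternion oracle", {
  set.seed(7)
  src <- muscleArch:::.defaultMarkerLayoutMr()[1:4, ]
  R <- muscleArch:::.axisAngleRotation(c(0.2, -1, 0.5), 38)
  tr <- rigidTransform(R, c(12, -7, 30))
  rotErr <- numeric(0)
  for (i in 1:25) {
    dst <- applyTransform(tr, src) + matrix(rnorm(12, sd = 0.5), 4, 3)
    fit <- fitRigidTransform(src, dst)
    orac <- oracleRigidFitQuaternion(src, dst)
    expect_lt(max(abs(fit@rotation - orac$rotation)), 1e-8)
    expect_lt(max(abs(fit@translation - orac$translation)), 1e-6)
    rotErr <- c(rotErr, rotationAngleDeg(fit@rotation, R))
    # rigidity: inter-marker distances preserved
    d0 <- dist(src); d1 <- dist(applyTransform(fit, src))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
  expect_lt(mean(rotErr), 1)
})

test_that("degenerate clusters and reflections are handled", {
  line <- cbind(1:4, 0, 0)
  expect_error(fitRigidTransform(line, line * 2), "collinear")
  # mirrored correspondence: the optimal orthogonal map is a reflection;
  # the fit must still return a proper rotation
  src <- muscleArch:::.defaultMarkerLayoutMr()[1:4, ]
  dst <- src %*% diag(c(-1, 1, 1))
  fit <- fitRigidTransform(src, dst)
  expect_equal(det(fit@rotation), 1, tolerance = 1e-9)
})

test_that("the scan plane is built from the probe markers", {
  pl <- scanPlaneFromProbe(c(0, 0, 0), c(38, 0, 0), c(19, 10, 0))
  expect_equal(abs(pl@normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl@fovWidth, 38, tolerance = 1e-12)
  expect_equal(pl@lateral, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(pl@depth, c(0, -1, 0), tolerance = 1e-12)  # away from AU
  expect_error(scanPlaneFromProbe(c(0, 0, 0), c(38, 0, 0), c(19, 0, 0)),
               "collinear")

  # plane parameters transform covariantly under a rigid motion
  R <- muscleArch:::.axisAngleRotation(c(1, 2, -1), 55)
  tr <- rigidTransform(R, c(3, -40, 18))
  plT <- scanPlaneFromProbe(applyTransform(tr, c(0, 0, 0)),
                            applyTransform(tr, c(38, 0, 0)),
                            applyTransform(tr, c(19, 10, 0)))
  expect_equal(plT@origin, applyTransform(tr, pl@origin),
               tolerance = 1e-9)
  expect_equal(plT@lateral, drop(R %*% pl@lateral), tolerance = 1e-9)
  expect_equal(plT@depth, drop(R %*% pl@depth), tolerance = 1e-9)
})

test_that("the located plane matches the truth built directly in MR", {
  R <- muscleArch:::.axisAngleRotation(c(0, 1, 1), 25)
  tr <- rigidTransform(R, c(20, 5, -30))
  sc <- makeMarkerScene(tr, noiseSdMm = 0)
  pl <- locateUsPlaneInMr(sc)
  lay <- muscleArch:::.defaultMarkerLayoutMr()
  plTrue <- scanPlaneFromProbe(lay["AL", ], lay["AR", ], lay["AU", ])
  expect_lt(max(abs(pl@origin - plTrue@origin)), 1e-8)
  expect_lt(max(abs(pl@normal - plTrue@normal)), 1e-8)

  # noisy markers: plane accurate to the expected tolerances
  errO <- c(); errN <- c()
  for (i in 1:20) {
    scN <- makeMarkerScene(tr, noiseSdMm = 0.5, rngSeed = 3L + i)
    plN <- locateUsPlaneInMr(scN)
    errO <- c(errO, sqrt(sum((plN@origin - plTrue@origin)^2)))
    errN <- c(errN, angleBetweenDeg(plN@normal, plTrue@normal))
  }
  expect_lt(mean(errO), 1.5)
  expect_lt(mean(errN), 1.5)

  scBad <- sc
  scBad@markers <- scBad@markers[scBad@markers$label != "P3", ]
  expect_error(locateUsPlaneInMr(scBad), "P3")
})

test_that("seeding at the plane-muscle intersection hits the muscle", {
  ph <- makeUnipennatePhantom(phantomSpec(12, 30, muscleLengthMm = 90,
                                          voxelSizeMm = 1))
  lm <- phantomLabelMap(ph)
  mesh <- meshFromLabelMap(lm$labels, lm$affine)
  pl <- scanPlaneFromProbe(c(0, 26, 30), c(0, 64, 30), c(0, 45, 45))
  sr <- seedFromIntersection(pl, mesh)
  # seed center voxel carries label 1
  ijk <- round(solve(ph@affine) %*% c(sr@center, 1))[1:3] + 1
  expect_equal(ph@labels[ijk[1], ijk[2], ijk[3]], 1L)

  # centroid equals the brute-force fan-triangulation centroid
  polys <- planeMeshIntersection(pl, mesh, bounded = TRUE)
  polys <- Filter(function(p) isTRUE(attr(p, "closed")), polys)
  poly <- attr(polys[[1]], "planeCoords")
  n <- nrow(poly)
  aSum <- 0; cSum <- c(0, 0)
  for (i in 2:(n - 1)) {
    a <- poly[1, ]; b <- poly[i, ]; cc <- poly[i + 1, ]
    ar <- ((b[1] - a[1]) * (cc[2] - a[2]) -
             (cc[1] - a[1]) * (b[2] - a[2])) / 2
    aSum <- aSum + ar
    cSum <- cSum + ar * (a + b + cc) / 3
  }
  ctr2d <- cSum / aSum
  ctr3d <- pl@origin + ctr2d[1] * pl@lateral + ctr2d[2] * pl@depth
  expect_equal(sr@center, ctr3d, tolerance = 1e-9)

  # three sites are spread along the intersection
  srs <- seedFromIntersection(pl, mesh, nSites = 3)
  expect_length(srs, 3)
  lats <- sapply(srs, function(s) sum((s@center - pl@origin) * pl@lateral))
  expect_true(all(diff(lats) > 5))

  plOut <- scanPlaneFromProbe(c(0, 26, 230), c(0, 64, 230),
                              c(0, 45, 245))
  expect_error(seedFromIntersection(plOut, mesh), "no in-field-of-view")
})
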