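# Surface meshes from label maps and the geometric primitives on them.

test_that("label-map meshes reproduce analytic volume and area", {
  lab <- array(0L, c(26, 26, 26))
  lab[4:23, 4:23, 4:23] <- 1L          # 20 mm cube at 1 mm voxels
  m <- meshFromLabelMap(lab, diag(4))
  expect_lt(abs(meshVolume(m) / 8000 - 1), 0.05)

  n <- 36; cc <- (n + 1) / 2
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  r2 <- rowSums((g - cc)^2)
  sph <- array(as.integer(r2 <= 15^2), c(n, n, n))
  m2 <- meshFromLabelMap(sph, diag(4))
  expect_lt(abs(meshArea(m2) / (4 * pi * 15^2) - 1), 0.03)

  expect_error(meshFromLabelMap(array(0L, c(5, 5, 5)), diag(4)), "empty")
  full <- array(1L, c(5, 5, 5))
  expect_error(meshFromLabelMap(full, diag(4)), "pad")
})

test_that("Taubin smoothing is shrink-free on convex fixtures", {
  n <- 36; cc <- (n + 1) / 2
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  sph <- array(as.integer(rowSums((g - cc)^2) <= 15^2), c(n, n, n))
  raw <- meshFromLabelMap(sph, diag(4), smoothingIterations = 0,
                          fieldSigmaVox = 0)
  smo <- meshFromLabelMap(sph, diag(4), smoothingIterations = 10,
                          fieldSigmaVox = 0)
  expect_lt(abs(meshVolume(smo) / meshVolume(raw) - 1), 0.02)
})

test_that("emitted meshes have unit outward normals and positive volume", {
  for (m in list(cubeMesh(20), icosphereMesh(15, 3))) {
    expect_lt(max(abs(sqrt(rowSums(m@normals^2)) - 1)), 1e-9)
    expect_gt(meshVolume(m), 0)
  }
  lab <- array(0L, c(16, 16, 16)); lab[5:12, 5:12, 5:12] <- 1L
  m <- meshFromLabelMap(lab, diag(4))
  expect_lt(max(abs(sqrt(rowSums(m@normals^2)) - 1)), 1e-9)
  expect_gt(meshVolume(m), 0)
})

test_that("clustering decimation reduces triangles without gross bias", {
  n <- 30; cc <- (n + 1) / 2
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  sph <- array(as.integer(rowSums((g - cc)^2) <= 12^2), c(n, n, n))
  full <- meshFromLabelMap(sph, diag(4))
  dec <- meshFromLabelMap(sph, diag(4), decimationFraction = 0.7)
  expect_lt(nrow(dec@triangles), 0.6 * nrow(full@triangles))
  expect_lt(abs(meshVolume(dec) / meshVolume(full) - 1), 0.1)
})

test_that("ray casting returns the nearest hit or nothing", {
  cube <- cubeMesh(20)
  hit <- rayMeshFirstHit(cube, c(0, 0, 0), c(0, 0, 1))
  expect_equal(hit$point, c(0, 0, 10), tolerance = 1e-9)
  expect_equal(hit$t, 10, tolerance = 1e-9)

  slab <- openSlabMesh(0, 10)
  expect_null(rayMeshFirstHit(slab, c(0, 0, 5), c(1, 0, 0)))
  expect_error(rayMeshFirstHit(cube, c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("ray casting agrees with the brute-force oracle on random rays", {
  sph <- icosphereMesh(20, 2)
  set.seed(99)
  nRays <- 200
  for (i in seq_len(nRays)) {
    o <- rnorm(3, sd = 8)
    d <- rnorm(3)
    mine <- rayMeshFirstHit(sph, o, d)
    orac <- oracleRayMeshHit(sph, o, d)
    if (is.null(orac)) {
      expect_null(mine)
    } else {
      expect_false(is.null(mine))
      expect_equal(mine$t, orac$t, tolerance = 1e-8)
      expect_equal(mine$point, orac$point, tolerance = 1e-7)
    }
  }
})

test_that("local mean normals average the surrounding surface", {
  slab <- openSlabMesh(0, 10, half = 50)
  n <- localMeanNormal(slab, c(0, 0, 10), radiusMm = 5)
  expect_equal(abs(n[3]), 1, tolerance = 1e-12)

  sph <- icosphereMesh(20, 4)
  nPole <- localMeanNormal(sph, c(0, 0, 20), radiusMm = 5)
  expect_lt(angleBetweenDeg(nPole, c(0, 0, 1)), 1)
  # brute-force area-weighted average over the same triangle set
  ctr <- (sph@vertices[sph@triangles[, 1], ] +
            sph@vertices[sph@triangles[, 2], ] +
            sph@vertices[sph@triangles[, 3], ]) / 3
  sel <- rowSums(sweep(ctr, 2, c(0, 0, 20))^2) <= 25
  ar <- muscleArch:::.triangleAreas(sph@vertices, sph@triangles)[sel]
  bf <- colSums(sph@normals[sel, ] * ar)
  bf <- bf / sqrt(sum(bf^2))
  expect_equal(unname(n <- localMeanNormal(sph, c(0, 0, 20), 5)), bf,
               tolerance = 1e-9)

  expect_error(localMeanNormal(sph, c(0, 0, 200), radiusMm = 5), "radius")
})

test_that("plane cross-sections reproduce analytic section curves", {
  plane <- new("ScanPlane", origin = c(0, 0, 0), normal = c(0, 0, 1),
               lateral = c(1, 0, 0), depth = c(0, 1, 0), fovWidth = 10,
               fovDepth = 10)
  sph <- icosphereMesh(20, 4)
  polys <- planeMeshIntersection(plane, sph, bounded = FALSE)
  expect_length(polys, 1)
  expect_true(attr(polys[[1]], "closed"))
  expect_lt(abs(polylineLength(polys[[1]]) / (2 * pi * 20) - 1), 0.01)

  planeOut <- new("ScanPlane", origin = c(0, 0, 100), normal = c(0, 0, 1),
                  lateral = c(1, 0, 0), depth = c(0, 1, 0), fovWidth = 10,
                  fovDepth = 10)
  expect_length(planeMeshIntersection(planeOut, sph, bounded = FALSE), 0)

  cube <- cubeMesh(20)
  pc <- planeMeshIntersection(plane, cube, bounded = FALSE)
  expect_length(pc, 1)
  expect_true(attr(pc[[1]], "closed"))
  expect_equal(polylineLength(pc[[1]]), 80, tolerance = 1e-9)
})

test_that("bounded cross-sections are clipped to the field of view", {
  plane <- new("ScanPlane", origin = c(0, 0, 0), normal = c(0, 0, 1),
               lateral = c(1, 0, 0), depth = c(0, 1, 0), fovWidth = 20,
               fovDepth = 10)
  cube <- cubeMesh(20)
  polys <- planeMeshIntersection(plane, cube, bounded = TRUE)
  expect_gt(length(polys), 0)
  for (p in polys) {
    q <- attr(p, "planeCoords")
    expect_true(all(q[, 1] >= -10 - 1e-9 & q[, 1] <= 10 + 1e-9))
    expect_true(all(q[, 2] >= -1e-9 & q[, 2] <= 10 + 1e-9))
  }
})
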