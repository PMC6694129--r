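# Fixtures built in code and independent oracle implementations used
# across the test files. Oracles deliberately use different algorithms
# from the package code paths they check.

# --- analytic meshes -------------------------------------------------------

# Axis-aligned cube mesh (12 triangles), centered at `center`, edge `edge`,
# outward orientation.
cubeMesh <- function(edge = 20, center = c(0, 0, 0)) {
  h <- edge / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2L, center, "+")
  # faces as vertex indices into the expand.grid order (x fastest)
  quads <- rbind(
    c(1, 3, 4, 2),  # z = -h (viewed from below)
    c(5, 6, 8, 7),  # z = +h
    c(1, 2, 6, 5),  # y = -h
    c(3, 7, 8, 4),  # y = +h
    c(1, 5, 7, 3),  # x = -h
    c(2, 4, 8, 6))  # x = +h
  tri <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i)
    rbind(quads[i, c(1, 2, 3)], quads[i, c(1, 3, 4)])))
  surfaceMesh(v, tri)
}

# Subdivided icosahedron projected onto a sphere.
icosphereMesh <- function(radius = 20, subdivisions = 4,
                          center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      k <- edgeKey(a, b)
      id <- mids[[k]]
      if (is.null(id)) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        id <- nrow(v)
        mids[[k]] <- id
      }
      id
    }
    nf <- list()
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[[length(nf) + 1]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                    c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2L, center, "+")
  surfaceMesh(v, f)
}

# Open slab mesh: two parallel rectangular faces at z = z0 and z = z1
# (no side walls, so rays parallel to the faces miss), each triangulated
# on a grid fine enough for 5 mm local-normal neighborhoods.
openSlabMesh <- function(z0 = 0, z1 = 10, half = 100, cell = 2.5) {
  xs <- seq(-half, half, by = cell)
  grid2d <- function(z, flip) {
    nv <- length(xs)
    v <- cbind(rep(xs, nv), rep(xs, each = nv), z)
    tri <- list()
    for (j in seq_len(nv - 1)) for (i in seq_len(nv - 1)) {
      a <- (j - 1) * nv + i
      tri[[length(tri) + 1]] <- rbind(c(a, a + 1, a + nv + 1),
                                      c(a, a + nv + 1, a + nv))
    }
    tri <- do.call(rbind, tri)
    if (flip) tri <- tri[, c(1, 3, 2)]
    list(v = v, tri = tri)
  }
  bot <- grid2d(z0, flip = TRUE)    # normal -z
  top <- grid2d(z1, flip = FALSE)   # normal +z
  v <- rbind(bot$v, top$v)
  tri <- rbind(bot$tri, top$tri + nrow(bot$v))
  new("SurfaceMesh", vertices = v, triangles = tri,
      normals = muscleArch:::.triangleNormals(v, tri))
}

# Wedge: bottom face z = 0, top face z = 10 + slope * y. With slope 0.2
# the vertical thickness at y = -5, 0, 5 is 9, 10, 11.
wedgeMesh <- function(slope = 0.2, half = 100) {
  v <- rbind(
    c(-half, -half, 0), c(half, -half, 0), c(half, half, 0),
    c(-half, half, 0),
    c(-half, -half, 10 - slope * half), c(half, -half, 10 - slope * half),
    c(half, half, 10 + slope * half), c(-half, half, 10 + slope * half))
  tri <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8))
  new("SurfaceMesh", vertices = v, triangles = tri,
      normals = muscleArch:::.triangleNormals(v, tri))
}

# --- synthetic tensor volumes ---------------------------------------------

tensorWithDirection <- function(dir, fa = 0.35, md = 1.5e-3) {
  lam <- muscleArch:::.prolateEigenvalues(fa, md)
  muscleArch:::.tensorFromFrame(lam, dir / sqrt(sum(dir^2)))
}

# Uniform tensor field with principal direction `dir` inside an axis
# aligned slab of `extent` mm (1 mm voxels), low-FA outside.
uniformTensorVolume <- function(dir = c(1, 0, 0), extent = c(60, 20, 20),
                                fa = 0.35, faOut = 0.05) {
  pad <- 3L
  dims <- as.integer(extent) + 2L * pad
  aff <- diag(4); aff[1:3, 4] <- -pad + 0.5
  Din <- tensorWithDirection(dir, fa)
  Dout <- tensorWithDirection(c(1, 0, 0), faOut)
  comp <- function(D) c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3],
                        D[3, 3])
  xc <- aff[1, 4] + seq_len(dims[1]) - 1
  yc <- aff[2, 4] + seq_len(dims[2]) - 1
  zc <- aff[3, 4] + seq_len(dims[3]) - 1
  inside <- outer(outer(xc >= 0 & xc <= extent[1],
                        yc >= 0 & yc <= extent[2], "&"),
                  zc >= 0 & zc <= extent[3], "&")
  tens <- array(0, c(dims, 6L))
  ci <- comp(Din); co <- comp(Dout)
  for (m in 1:6) tens[, , , m] <- ifelse(inside, ci[m], co[m])
  tensorVolume(tens, aff)
}

# Circular-arc field: principal direction tangent to circles around the
# volume center axis (z), constant FA everywhere.
arcTensorVolume <- function(dims = c(60L, 60L, 8L), fa = 0.35) {
  aff <- diag(4)
  aff[1:3, 4] <- -(dims - 1) / 2
  tens <- array(0, c(dims, 6L))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    x <- aff[1, 4] + i - 1; y <- aff[2, 4] + j - 1
    r <- sqrt(x^2 + y^2)
    d <- if (r < 1e-6) c(1, 0, 0) else c(-y, x, 0) / r
    D <- tensorWithDirection(d, fa)
    cmp <- c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
    for (m in 1:6) tens[i, j, , m] <- cmp[m]
  }
  tensorVolume(tens, aff)
}

# --- oracles ---------------------------------------------------------------

# Independent ray-triangle oracle: plane intersection followed by a
# barycentric inside test (different algorithm from Moller-Trumbore).
oracleRayMeshHit <- function(mesh, origin, direction, tol = 1e-9) {
  d <- direction / sqrt(sum(direction^2))
  V <- mesh@vertices; Tm <- mesh@triangles
  best <- NULL
  for (i in seq_len(nrow(Tm))) {
    a <- V[Tm[i, 1], ]; b <- V[Tm[i, 2], ]; cc <- V[Tm[i, 3], ]
    n <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
           (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
           (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    dn <- sum(d * n)
    if (abs(dn) < 1e-14) next
    t <- sum((a - origin) * n) / dn
    if (t <= tol) next
    p <- origin + t * d
    # barycentric via dot products
    v0 <- cc - a; v1 <- b - a; v2 <- p - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= -1e-9 && v >= -1e-9 && u + v <= 1 + 1e-9) {
      if (is.null(best) || t < best$t)
        best <- list(point = p, t = t, triangle = i)
    }
  }
  best
}

# Horn's quaternion absolute-orientation oracle for the rigid fit.
oracleRigidFitQuaternion <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  S <- crossprod(A, B)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    3, 3)
  list(rotation = R, translation = cd - drop(R %*% cs))
}

# Full 2^n enumeration oracle for the exact Wilcoxon signed-rank p-value.
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  pLo <- mean(Ws <= W + 1e-12)
  pHi <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(pLo, pHi))
}

rotationAngleDeg <- function(R1, R2) {
  R <- R1 %*% t(R2)
  ca <- (sum(diag(R)) - 1) / 2
  acos(min(max(ca, -1), 1)) * 180 / pi
}

angleBetweenDeg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a * a) * sum(b * b))
  acos(min(max(ca, 0), 1)) * 180 / pi
}

# three bundles evenly spaced along the phantom's long axis, via the
# synthetic-tract generator shifted to three sites
phantomBundles <- function(ph, seeds = 1:3, jitter = NULL, trunc = NULL) {
  spec <- ph@spec
  lapply(seq_along(seeds), function(i) {
    sp <- spec
    if (!is.null(jitter)) sp@endpointJitterSdMm <- jitter
    if (!is.null(trunc)) sp@truncationMm <- trunc
    synthesizeTracts(ph, sp, rngSeed = seeds[i])
  })
}
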