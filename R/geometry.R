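# Geometric primitives on surface meshes: ray casting, local surface
# normals, plane/mesh cross-sections and 2D polygon utilities.

#' First intersection of a ray with a mesh
#'
#' Tests the ray against every triangle (Moller-Trumbore) and returns the
#' nearest hit with parameter `t > tol`. Absence of a hit is a value
#' (`NULL`), not an error.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param origin world-mm ray origin.
#' @param direction ray direction (need not be unit; `t` is in units of its
#'   length).
#' @param tol minimum accepted ray parameter, guarding against self-hits
#'   when the origin lies on the surface.
#' @return `NULL` if the ray misses, else a list with `point` (mm),
#'   `t` (distance along the unit direction, mm) and `triangle` (index).
#' @export
rayMeshFirstHit <- function(mesh, origin, direction, tol = 1e-9) {
  if (.vnorm(direction) < .Machine$double.eps)
    stop("ray direction must be nonzero")
  d <- .unitv(direction)
  V <- mesh@vertices; Tm <- mesh@triangles
  v0 <- V[Tm[, 1L], , drop = FALSE]
  e1 <- V[Tm[, 2L], , drop = FALSE] - v0
  e2 <- V[Tm[, 3L], , drop = FALSE] - v0
  h <- cbind(d[2L] * e2[, 3L] - d[3L] * e2[, 2L],
             d[3L] * e2[, 1L] - d[1L] * e2[, 3L],
             d[1L] * e2[, 2L] - d[2L] * e2[, 1L])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  f <- ifelse(ok, 1 / a, NA_real_)
  s <- -sweep(v0, 2L, origin)
  u <- f * rowSums(s * h)
  q <- cbind(s[, 2L] * e1[, 3L] - s[, 3L] * e1[, 2L],
             s[, 3L] * e1[, 1L] - s[, 1L] * e1[, 3L],
             s[, 1L] * e1[, 2L] - s[, 2L] * e1[, 1L])
  v <- f * drop(q %*% d)
  tpar <- f * rowSums(e2 * q)
  eps <- 1e-9
  hit <- ok & !is.na(u) & u >= -eps & v >= -eps & (u + v) <= 1 + eps &
    tpar > tol
  if (!any(hit)) return(NULL)
  idx <- which(hit)
  best <- idx[which.min(tpar[idx])]
  list(point = origin + tpar[best] * d, t = tpar[best], triangle = best)
}

#' Area-weighted mean surface normal around a point
#'
#' Averages the unit normals of all triangles whose centroids lie within
#' `radiusMm` of `point`, weighting by triangle area (or unweighted), and
#' renormalizes.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param point world-mm query point (typically a fascicle endpoint on the
#'   surface).
#' @param radiusMm inclusion radius for triangle centroids; default 5 mm.
#' @param areaWeighted use area weights (default) or a plain mean.
#' @return Unit 3-vector.
#' @export
localMeanNormal <- function(mesh, point, radiusMm = 5, areaWeighted = TRUE) {
  ctr <- .triangleCentroids(mesh@vertices, mesh@triangles)
  d2 <- rowSums(sweep(ctr, 2L, point)^2)
  sel <- d2 <= radiusMm^2
  if (!any(sel))
    stop(sprintf(
      "no triangle centroid within %.3g mm of the point; use a larger radius",
      radiusMm))
  w <- if (areaWeighted)
    .triangleAreas(mesh@vertices, mesh@triangles)[sel] else rep(1, sum(sel))
  n <- colSums(mesh@normals[sel, , drop = FALSE] * w)
  .unitv(n)
}

# interpolate the zero crossing of signed distances along triangle edges
# and return one segment per crossing triangle (n x 6: p1, p2)
.planeTriangleSegments <- function(plane, mesh) {
  V <- mesh@vertices
  s <- drop(sweep(V, 2L, plane@origin) %*% plane@normal)
  s[s == 0] <- 1e-12               # nudge on-plane vertices to one side
  Tm <- mesh@triangles
  s1 <- s[Tm[, 1L]]; s2 <- s[Tm[, 2L]]; s3 <- s[Tm[, 3L]]
  cross12 <- (s1 > 0) != (s2 > 0)
  cross23 <- (s2 > 0) != (s3 > 0)
  cross13 <- (s1 > 0) != (s3 > 0)
  any2 <- cross12 + cross23 + cross13 == 2L
  if (!any(any2)) return(NULL)
  idx <- which(any2)
  ipt <- function(a, b, sa, sb) {
    w <- sa / (sa - sb)
    V[a, , drop = FALSE] + w * (V[b, , drop = FALSE] - V[a, , drop = FALSE])
  }
  seg <- matrix(NA_real_, length(idx), 6L)
  for (r in seq_along(idx)) {
    i <- idx[r]
    pts <- list()
    if (cross12[i]) pts[[length(pts) + 1L]] <-
        ipt(Tm[i, 1L], Tm[i, 2L], s1[i], s2[i])
    if (cross23[i]) pts[[length(pts) + 1L]] <-
        ipt(Tm[i, 2L], Tm[i, 3L], s2[i], s3[i])
    if (cross13[i]) pts[[length(pts) + 1L]] <-
        ipt(Tm[i, 1L], Tm[i, 3L], s1[i], s3[i])
    seg[r, ] <- c(pts[[1L]], pts[[2L]])
  }
  seg
}

# stitch unordered segments (n x 6) into polylines by matching endpoints
.stitchSegments <- function(seg, digits = 6L) {
  n <- nrow(seg)
  p1 <- seg[, 1:3, drop = FALSE]; p2 <- seg[, 4:6, drop = FALSE]
  key <- function(p) paste(round(p[, 1L], digits), round(p[, 2L], digits),
                           round(p[, 3L], digits))
  k1 <- key(p1); k2 <- key(p2)
  allk <- unique(c(k1, k2))
  adj <- vector("list", length(allk))
  names(adj) <- allk
  for (i in seq_len(n)) {
    adj[[k1[i]]] <- rbind(adj[[k1[i]]], c(i, 1L))
    adj[[k2[i]]] <- rbind(adj[[k2[i]]], c(i, 2L))
  }
  used <- logical(n)
  out <- list()
  walk <- function(start, startEnd) {
    pts <- list()
    i <- start; endUsed <- startEnd
    first <- if (startEnd == 1L) p1[i, ] else p2[i, ]
    pts[[1L]] <- first
    repeat {
      used[i] <<- TRUE
      nxt <- if (endUsed == 1L) p2[i, ] else p1[i, ]
      pts[[length(pts) + 1L]] <- nxt
      nk <- paste(round(nxt[1L], digits), round(nxt[2L], digits),
                  round(nxt[3L], digits))
      cand <- adj[[nk]]
      cand <- cand[!used[cand[, 1L]], , drop = FALSE]
      if (is.null(cand) || nrow(cand) == 0L) break
      i <- cand[1L, 1L]; endUsed <- cand[1L, 2L]
    }
    do.call(rbind, pts)
  }
  deg <- vapply(adj, nrow, integer(1))
  # open chains first (endpoints of degree 1)
  for (k in allk[deg == 1L]) {
    e <- adj[[k]]
    e <- e[!used[e[, 1L]], , drop = FALSE]
    if (nrow(e) == 0L) next
    out[[length(out) + 1L]] <- walk(e[1L, 1L], e[1L, 2L])
  }
  # remaining loops
  for (i in seq_len(n)) {
    if (used[i]) next
    out[[length(out) + 1L]] <- walk(i, 1L)
  }
  lapply(out, function(p) {
    closed <- sum((p[1L, ] - p[nrow(p), ])^2) < (10^(-digits))^2
    if (closed) p <- p[-nrow(p), , drop = FALSE]
    attr(p, "closed") <- closed
    p
  })
}

#' Cross-section of a mesh by a scan plane
#'
#' Clips every triangle against the plane and stitches the resulting
#' segments into polylines. With `bounded = TRUE` the polylines are further
#' clipped to the plane's rectangular field of view (lateral within
#' half the FOV width of the origin, depth in `[0, fovDepth]`).
#'
#' @param plane a [ScanPlane-class].
#' @param mesh a [SurfaceMesh-class].
#' @param bounded clip to the field of view (default `TRUE`).
#' @return A list of polylines: n x 3 matrices of world-mm points, each
#'   with attributes `closed` (logical) and `planeCoords` (n x 2 matrix of
#'   in-plane lateral/depth coordinates). Empty list if no intersection.
#' @export
planeMeshIntersection <- function(plane, mesh, bounded = TRUE) {
  seg <- .planeTriangleSegments(plane, mesh)
  if (is.null(seg)) return(list())
  len2 <- rowSums((seg[, 1:3, drop = FALSE] - seg[, 4:6, drop = FALSE])^2)
  seg <- seg[len2 > 1e-16, , drop = FALSE]
  if (nrow(seg) == 0L) return(list())
  polys <- .stitchSegments(seg)
  to2d <- function(p) {
    rel <- sweep(p, 2L, plane@origin)
    cbind(drop(rel %*% plane@lateral), drop(rel %*% plane@depth))
  }
  if (bounded) {
    w2 <- plane@fovWidth / 2
    rect <- c(-w2, 0, w2, plane@fovDepth)   # xmin, ymin, xmax, ymax
    out <- list()
    for (p in polys) {
      pieces <- .clipPolylineRect(to2d(p), rect, closed = attr(p, "closed"))
      for (q in pieces) {
        p3 <- matrix(plane@origin, nrow(q), 3L, byrow = TRUE) +
          q[, 1L] %o% plane@lateral + q[, 2L] %o% plane@depth
        attr(p3, "closed") <- attr(q, "closed")
        attr(p3, "planeCoords") <- q
        out[[length(out) + 1L]] <- p3
      }
    }
    out
  } else {
    lapply(polys, function(p) {
      attr(p, "planeCoords") <- to2d(p)
      p
    })
  }
}

#' Arc length of a polyline
#' @param p n x d matrix of points; with attribute `closed = TRUE` the
#'   closing segment is included.
#' @return Total length.
#' @export
polylineLength <- function(p) {
  if (isTRUE(attr(p, "closed"))) p <- rbind(p, p[1L, ])
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# --- 2D polygon helpers ----------------------------------------------------

.polyArea <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

.polyCentroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Sutherland-Hodgman clip of a closed polygon against an axis-aligned rect
.clipPolyRect <- function(p, rect) {
  clipHalf <- function(p, keep, cross) {
    if (nrow(p) == 0L) return(p)
    out <- list()
    n <- nrow(p)
    for (i in seq_len(n)) {
      cur <- p[i, ]; prv <- p[if (i == 1L) n else i - 1L, ]
      ck <- keep(cur); pk <- keep(prv)
      if (ck) {
        if (!pk) out[[length(out) + 1L]] <- cross(prv, cur)
        out[[length(out) + 1L]] <- cur
      } else if (pk) {
        out[[length(out) + 1L]] <- cross(prv, cur)
      }
    }
    if (!length(out)) matrix(numeric(0), 0L, 2L) else do.call(rbind, out)
  }
  ix <- function(a, b, v, ax) {  # crossing with line coord v on axis ax
    t <- (v - a[ax]) / (b[ax] - a[ax])
    a + t * (b - a)
  }
  p <- clipHalf(p, function(q) q[1L] >= rect[1L],
                function(a, b) ix(a, b, rect[1L], 1L))
  p <- clipHalf(p, function(q) q[2L] >= rect[2L],
                function(a, b) ix(a, b, rect[2L], 2L))
  p <- clipHalf(p, function(q) q[1L] <= rect[3L],
                function(a, b) ix(a, b, rect[3L], 1L))
  p <- clipHalf(p, function(q) q[2L] <= rect[4L],
                function(a, b) ix(a, b, rect[4L], 2L))
  p
}

# Clip an open/closed 2D polyline to a rectangle; returns a list of pieces.
.clipPolylineRect <- function(p, rect, closed = FALSE) {
  if (closed) {
    q <- .clipPolyRect(p, rect)
    if (nrow(q) < 3L) return(list())
    # fully inside and unchanged -> still closed polygon
    attr(q, "closed") <- TRUE
    return(list(q))
  }
  pieces <- list(); cur <- list()
  flush <- function() {
    if (length(cur) >= 2L) {
      m <- do.call(rbind, cur)
      attr(m, "closed") <- FALSE
      pieces[[length(pieces) + 1L]] <<- m
    }
    cur <<- list()
  }
  clipSeg <- function(a, b) {
    # Liang-Barsky
    d <- b - a; t0 <- 0; t1 <- 1
    for (side in 1:4) {
      pp <- switch(side, -d[1L], d[1L], -d[2L], d[2L])
      qq <- switch(side, a[1L] - rect[1L], rect[3L] - a[1L],
                   a[2L] - rect[2L], rect[4L] - a[2L])
      if (abs(pp) < 1e-15) { if (qq < 0) return(NULL) }
      else {
        r <- qq / pp
        if (pp < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
        if (t0 > t1) return(NULL)
      }
    }
    rbind(a + t0 * d, a + t1 * d)
  }
  for (i in seq_len(nrow(p) - 1L)) {
    sc <- clipSeg(p[i, ], p[i + 1L, ])
    if (is.null(sc)) { flush(); next }
    if (!length(cur)) cur <- list(sc[1L, ])
    else {
      lastPt <- cur[[length(cur)]]
      if (sum((lastPt - sc[1L, ])^2) > 1e-18) { flush(); cur <- list(sc[1L, ]) }
    }
    cur[[length(cur) + 1L]] <- sc[2L, ]
  }
  flush()
  pieces
}
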