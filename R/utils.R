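# Small internal helpers shared across modules. All geometry is in world mm.

.vnorm <- function(v) sqrt(sum(v * v))

.unitv <- function(v) {
  n <- .vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Unsigned acute angle (degrees) between two directions, treated as lines
# (sign of either vector is irrelevant).
.lineAngleDeg <- function(a, b) {
  ca <- abs(sum(a * b)) / (.vnorm(a) * .vnorm(b))
  .rad2deg(acos(.clamp(ca, -1, 1)))
}

# Angle (degrees) between two vectors, sign-sensitive.
.vecAngleDeg <- function(a, b) {
  ca <- sum(a * b) / (.vnorm(a) * .vnorm(b))
  .rad2deg(acos(.clamp(ca, -1, 1)))
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards. All stochastic operations in the package funnel
# through this so that results are reproducible from explicit seeds.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Apply a 4x4 affine to an n x 3 matrix of points (row-wise).
.applyAffine <- function(affine, pts) {
  pts <- rbind(t(pts), 1)
  out <- affine %*% pts
  t(out[1:3, , drop = FALSE])
}

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
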