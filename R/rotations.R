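# Rotation primitives: conversions among axis-angle, unit-quaternion and
# rotation-matrix forms, geodesic/chordal distances, SLERP, and the weighted
# quaternion mean used by every refiner in the package.
#
# Conventions (fixed package-wide):
#   * quaternions are scalar-first: (w, x, y, z);
#   * the canonical sign has a nonnegative scalar part (ties broken by the
#     first nonzero vector component being positive);
#   * vectorized functions take n x 3 / n x 4 matrices, one rotation per row,
#     and accept a bare vector as a single rotation.

# threshold below which angle-dependent ratios switch to series expansions
.SMALL_ANGLE <- 1e-8

.as_rows <- function(x, width, what) {
  if (is.null(dim(x))) {
    if (length(x) != width) {
      stop(sprintf("expected a length-%d vector or an n x %d matrix for %s",
                   width, width, what), call. = FALSE)
    }
    matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != width) {
      stop(sprintf("expected %d columns for %s, got %d", width, what, ncol(x)),
           call. = FALSE)
    }
    x
  }
}

.restore_shape <- function(res, input) {
  if (is.null(dim(input))) drop(res) else res
}

.check_unit_quat <- function(q, tol = 1e-6) {
  n <- sqrt(rowSums(q * q))
  if (any(!is.finite(n)) || any(abs(n - 1) > tol)) {
    stop("quaternion is not unit norm (within ", tol, ")", call. = FALSE)
  }
  invisible(n)
}

#' Canonicalize quaternion signs
#'
#' Flips the sign of each quaternion so that the scalar part is nonnegative;
#' when the scalar part is exactly zero the first nonzero vector component is
#' made positive.  `q` and `-q` encode the same rotation, so this is a pure
#' representation choice, applied everywhere the package writes poses out.
#'
#' @param q A length-4 quaternion `(w, x, y, z)` or an n x 4 matrix of them.
#' @return The sign-canonicalized quaternion(s), same shape as the input.
#' @export
quat_canonical <- function(q) {
  qm <- .as_rows(q, 4L, "quaternion")
  flip <- qm[, 1L] < 0
  zero_w <- qm[, 1L] == 0
  if (any(zero_w)) {
    for (i in which(zero_w)) {
      v <- qm[i, 2:4]
      nz <- which(v != 0)
      if (length(nz) > 0L && v[nz[1L]] < 0) flip[i] <- TRUE
    }
  }
  qm[flip, ] <- -qm[flip, , drop = FALSE]
  .restore_shape(qm, q)
}

#' Convert axis-angle rotations to unit quaternions
#'
#' The axis-angle vector `v` has the rotation axis as its direction and the
#' rotation angle (radians) as its norm; the zero vector is the identity.  The
#' result is `(cos(a/2), sin(a/2) * v / a)` with `a = |v|`, computed with a
#' series expansion of `sin(a/2)/a` below a small-angle threshold, and
#' sign-canonicalized.
#'
#' @param v A length-3 axis-angle vector or an n x 3 matrix of them.
#' @return Unit quaternion(s), scalar-first, canonical sign.
#' @export
axis_angle_to_quat <- function(v) {
  vm <- .as_rows(v, 3L, "axis-angle vector")
  if (any(!is.finite(vm))) stop("axis-angle input must be finite", call. = FALSE)
  ang <- sqrt(rowSums(vm * vm))
  half <- ang / 2
  # sin(a/2)/a = 1/2 - a^2/48 + O(a^4)
  k <- ifelse(ang < .SMALL_ANGLE, 0.5 - ang * ang / 48,
              sin(half) / pmax(ang, .Machine$double.xmin))
  q <- cbind(cos(half), vm * k)
  .restore_shape(quat_canonical(q), v)
}

#' Convert unit quaternions to axis-angle form
#'
#' Returns the rotation vector with angle in `[0, pi]`; the round trip through
#' [axis_angle_to_quat()] reproduces the quaternion up to sign.
#'
#' @param q A length-4 unit quaternion or an n x 4 matrix of them.
#' @return Axis-angle vector(s), same row layout as the input.
#' @export
quat_to_axis_angle <- function(q) {
  qm <- .as_rows(q, 4L, "quaternion")
  .check_unit_quat(qm)
  qm <- .as_rows(quat_canonical(qm), 4L, "quaternion")
  s <- sqrt(rowSums(qm[, 2:4, drop = FALSE]^2))
  w <- qm[, 1L]
  # angle = 2*atan2(s, w) in [0, pi]; scale = angle / s with series for s -> 0
  scale <- ifelse(s < .SMALL_ANGLE, 2 / pmax(w, .Machine$double.eps),
                  2 * atan2(s, w) / pmax(s, .Machine$double.xmin))
  .restore_shape(qm[, 2:4, drop = FALSE] * scale, q)
}

#' Convert a unit quaternion to a 3 x 3 rotation matrix
#'
#' @param q A length-4 unit quaternion `(w, x, y, z)`.
#' @return A proper orthogonal 3 x 3 matrix.
#' @export
quat_to_matrix <- function(q) {
  qm <- .as_rows(q, 4L, "quaternion")
  if (nrow(qm) != 1L) stop("quat_to_matrix() takes a single quaternion", call. = FALSE)
  .check_unit_quat(qm)
  w <- qm[1L]; x <- qm[2L]; y <- qm[3L]; z <- qm[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z),     1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
    2 * (x * z + w * y),     2 * (y * z - w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3L)
}

#' Hamilton product of quaternions
#'
#' Row-wise product `q1 * q2` (apply `q2` first, then `q1`, when quaternions
#' act on vectors by conjugation).  No sign canonicalization is applied.
#'
#' @param q1,q2 Length-4 quaternions or n x 4 matrices (recycled row-wise if
#'   one of them has a single row).
#' @return The product, same layout.
#' @export
quat_multiply <- function(q1, q2) {
  a <- .as_rows(q1, 4L, "quaternion"); b <- .as_rows(q2, 4L, "quaternion")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  res <- cbind(w, x, y, z, deparse.level = 0)
  if (is.null(dim(q1)) && is.null(dim(q2))) drop(res) else res
}

#' Quaternion conjugate
#' @param q Length-4 quaternion or n x 4 matrix.
#' @return The conjugate (inverse, for unit quaternions).
#' @export
quat_conjugate <- function(q) {
  qm <- .as_rows(q, 4L, "quaternion")
  res <- cbind(qm[, 1L], -qm[, 2:4, drop = FALSE], deparse.level = 0)
  .restore_shape(res, q)
}

#' Geodesic distance between rotations given as unit quaternions
#'
#' Angle (radians, in `[0, pi]`) of the relative rotation, computed through the
#' antipodally-minimal chord `c = min(|q1 - q2|, |q1 + q2|)` and
#' `theta = 4 asin(c / 2)`, which stays accurate for very small angles where an
#' arccos formulation loses all precision.
#'
#' @param q1,q2 Unit quaternions (length-4 or n x 4, recycled row-wise).
#' @return Rotation angle(s) in radians.
#' @export
quat_geodesic <- function(q1, q2) {
  a <- .as_rows(q1, 4L, "quaternion"); b <- .as_rows(q2, 4L, "quaternion")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  d1 <- sqrt(rowSums((a - b)^2))
  d2 <- sqrt(rowSums((a + b)^2))
  cmin <- pmin(d1, d2)
  res <- 4 * asin(pmin(1, cmin / 2))
  if (is.null(dim(q1)) && is.null(dim(q2))) drop(res) else res
}

#' Weighted mean of unit quaternions
#'
#' The normalized weighted sum of Eqs. "weighted averaging then normalization":
#' every quaternion is first hemisphere-aligned to a reference element (sign
#' flip when the dot product with the reference is negative), the weighted sum
#' is formed, and the result divided by its norm.  For rotations dispersed by a
#' small angle this is a second-order approximation of the chordal-L2 rotation
#' mean.  The reference defaults to the center element because, in refinement,
#' the window is centered on the frame being refined.
#'
#' @param quats n x 4 matrix of unit quaternions (rows).
#' @param weights Length-n nonnegative weights summing to 1 (within 1e-6).
#' @param ref_index Row used as the hemisphere-alignment reference; default the
#'   center row `floor(n/2) + 1`.
#' @return A single unit quaternion (canonical sign).
#' @export
weighted_quat_mean <- function(quats, weights, ref_index = (nrow(quats) - 1L) %/% 2L + 1L) {
  qm <- .as_rows(quats, 4L, "quaternion")
  n <- nrow(qm)
  if (length(weights) != n) stop("length(weights) must match nrow(quats)", call. = FALSE)
  if (any(weights < -1e-12)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1 (within 1e-6)", call. = FALSE)
  .check_unit_quat(qm)
  ref <- qm[ref_index, ]
  dots <- as.vector(qm %*% ref)
  sgn <- ifelse(dots < 0, -1, 1)
  s <- colSums(qm * (weights * sgn))
  nrm <- sqrt(sum(s * s))
  if (nrm < 1e-8) {
    stop(errorCondition("degenerate quaternion average: near-antipodal cancellation",
                        class = c("degenerate_average", "error", "condition")))
  }
  quat_canonical(s / nrm)
}

#' Spherical linear interpolation between two unit quaternions
#'
#' Constant-speed geodesic from `q1` (`t = 0`) to `q2` (`t = 1`), with `q2`
#' hemisphere-aligned to `q1` first.  For nearly identical inputs the
#' normalized linear interpolation limit is used.  The result lies on `q1`'s
#' hemisphere (no sign canonicalization), so `quat_slerp(q, q, t)` returns `q`
#' exactly.
#'
#' @param q1,q2 Length-4 unit quaternions.
#' @param t Interpolation parameter in `[0, 1]`.
#' @return A unit quaternion.
#' @export
quat_slerp <- function(q1, q2, t) {
  a <- .as_rows(q1, 4L, "quaternion"); b <- .as_rows(q2, 4L, "quaternion")
  if (nrow(a) != 1L || nrow(b) != 1L) stop("quat_slerp() takes single quaternions", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stop("t must be a single number in [0, 1]", call. = FALSE)
  }
  .check_unit_quat(a); .check_unit_quat(b)
  a <- drop(a); b <- drop(b)
  d <- sum(a * b)
  if (d < 0) { b <- -b; d <- -d }
  if (d > 1 - 1e-10) {
    out <- (1 - t) * a + t * b
    return(out / sqrt(sum(out * out)))
  }
  om <- acos(min(1, d))
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

.check_rotation_matrix <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L)) stop("expected a 3 x 3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0) {
    stop("matrix is not a proper rotation (within ", tol, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Squared chordal distance between two rotation matrices
#'
#' The squared Frobenius norm of `R1 - R2`; equal to `4 (1 - cos theta)` where
#' `theta` is the relative rotation angle.  This is the per-joint term of the
#' rotation (pose) loss.
#'
#' @param R1,R2 3 x 3 proper rotation matrices.
#' @return A nonnegative scalar in `[0, 8]`.
#' @export
chordal_sq_distance <- function(R1, R2) {
  .check_rotation_matrix(R1)
  .check_rotation_matrix(R2)
  sum((R1 - R2)^2)
}
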