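## Rigid transform algebra.
##
## Conventions (fixed across the whole package):
##   * quaternions are stored (w, x, y, z), Hamilton convention,
##     renormalized after every composition;
##   * a transform acts on a point p as p' = R p + t (right-handed frames);
##   * translations are millimetres, times are seconds.

QUAT_NORM_TOL <- 1e-9

#' Construct a rigid transform
#'
#' A rigid transform is a rotation (unit quaternion, `(w, x, y, z)` order,
#' Hamilton convention) plus a translation in millimetres.  It acts on a
#' column point `p` as `p' = R p + t`.
#'
#' @param q numeric(4) quaternion `(w, x, y, z)`; normalized on input.
#' @param t numeric(3) translation, mm.
#' @return An object of class `rigid_transform` with elements `q` and `t`.
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  q <- as.numeric(q); t <- as.numeric(t)
  stopifnot(length(q) == 4L, length(t) == 3L)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n < 1e-12)
    stop("rigid_transform: quaternion has (near) zero norm", call. = FALSE)
  structure(list(q = q / n, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform  q(wxyz) = [", paste(signif(x$q, 6), collapse = ", "),
      "]  t(mm) = [", paste(signif(x$t, 6), collapse = ", "), "]\n")
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

## Hamilton product of quaternions given as numeric(4) vectors.
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

## 3x3 rotation matrix from a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3, byrow = TRUE)
}

## Shepperd's method; returns (w,x,y,z) with w >= 0.
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Quaternion from axis-angle
#' @param axis numeric(3) rotation axis (normalized internally).
#' @param angle rotation angle, radians.
#' @return numeric(4) unit quaternion `(w, x, y, z)`.
#' @export
quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rigid transform from axis-angle rotation and translation
#' @inheritParams quat_axis_angle
#' @param t numeric(3) translation, mm.
#' @export
rt_axis_angle <- function(axis, angle, t = c(0, 0, 0))
  rigid_transform(quat_axis_angle(axis, angle), t)

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform mapping `p` to `a(b(p))`.  The
#' resulting quaternion is renormalized.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(quat_mul(a$q, b$q), as.numeric(quat_to_matrix(a$q) %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param x a `rigid_transform`.
#' @return A `rigid_transform` with `rt_compose(x, rt_invert(x))` = identity.
#' @export
rt_invert <- function(x) {
  stopifnot(is_rigid_transform(x))
  qi <- quat_conj(x$q)
  rigid_transform(qi, -as.numeric(quat_to_matrix(qi) %*% x$t))
}

#' Apply a rigid transform to points
#' @param x a `rigid_transform`.
#' @param p numeric(3) or an N x 3 matrix of points, mm.
#' @return Transformed points with the shape of the input.
#' @export
rt_apply <- function(x, p) {
  stopifnot(is_rigid_transform(x))
  R <- quat_to_matrix(x$q)
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    sweep(p %*% t(R), 2L, x$t, "+")
  } else {
    as.numeric(R %*% p) + x$t
  }
}

#' Convert to / from a 4x4 homogeneous matrix
#' @param x a `rigid_transform`.
#' @return `rt_to_matrix()`: a 4x4 homogeneous matrix.
#' @export
rt_to_matrix <- function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- quat_to_matrix(x$q)
  m[1:3, 4] <- x$t
  m
}

#' @rdname rt_to_matrix
#' @param m a 4x4 homogeneous rigid matrix.
#' @export
rt_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  rigid_transform(matrix_to_quat(m[1:3, 1:3]), m[1:3, 4])
}

## slerp of two unit quaternions along the shortest arc, u in [0,1].
quat_slerp <- function(q0, q1, u) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-12) {               # nearly parallel: nlerp is exact enough
    q <- (1 - u) * q0 + u * q1
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(min(1, d))
  (sin((1 - u) * th) * q0 + sin(u * th) * q1) / sin(th)
}

#' Interpolate between two timestamped poses
#'
#' Translation is interpolated linearly; rotation spherical-linearly along
#' the shortest arc (one quaternion is negated when their dot product is
#' negative).  No extrapolation: `t` must lie in `[t0, t1]`.
#'
#' @param t0,t1 bracketing times, seconds, `t0 < t1`.
#' @param p0,p1 `rigid_transform` poses at `t0` and `t1`.
#' @param t query time in `[t0, t1]`.
#' @return A `rigid_transform`.
#' @export
interpolate_pose <- function(t0, p0, t1, p1, t) {
  if (!(t0 < t1)) stop("interpolate_pose: need t0 < t1", call. = FALSE)
  if (t < t0 || t > t1)
    stop(errorCondition(sprintf(
      "interpolate_pose: t=%g outside [%g, %g] (no extrapolation)", t, t0, t1),
      class = c("sl_error_out_of_range", "error", "condition")))
  u <- (t - t0) / (t1 - t0)
  rigid_transform(quat_slerp(p0$q, p1$q, u), (1 - u) * p0$t + u * p1$t)
}

#' Rotation angle between two transforms
#' @param a,b `rigid_transform` objects.
#' @return Angle of the relative rotation, radians, in `[0, pi]`.
#' @export
rt_rotation_angle <- function(a, b = rt_identity()) {
  d <- abs(sum(a$q * b$q))
  2 * acos(min(1, d))
}

#' Draw a uniformly random rigid transform
#'
#' Rotation uniform on SO(3) (normalized Gaussian quaternion), translation
#' components uniform in `[-trans_range, trans_range]`.  Uses the current RNG
#' state.
#'
#' @param trans_range half-width of the translation cube, mm.
#' @export
rt_random <- function(trans_range = 100) {
  rigid_transform(stats::rnorm(4), stats::runif(3, -trans_range, trans_range))
}
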