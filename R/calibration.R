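## Calibration chain: pivot calibration for instrument tips, hand-eye
## calibration for the laparoscope (AX = XB from relative motions), and a
## closed-form point-based rigid registration used as the patient
## registration stand-in.

PIVOT_MAX_CONDITION <- 1e6        # conditioning threshold for pivot solve
HANDEYE_MIN_AXIS_SEP <- 5 * pi / 180  # min angle between motion axes, rad

#' Pivot calibration
#'
#' Estimates the tool-tip offset in the instrument-array frame and the fixed
#' pivot point in the tracker frame from poses recorded while pivoting the
#' tip about a fixed point.  Solves the stacked linear least-squares system
#' `[R_i | -I] [tip; pivot] = -t_i`.
#'
#' @param poses list of `rigid_transform` (tracker -> array), length >= 3.
#' @return A `pivot_result`: `tip_offset` (mm, array frame), `pivot_point`
#'   (mm, tracker frame), `rms_residual` (mm), `condition_number`.
#' @details The system is rank-deficient when all rotations are equal or
#'   share one axis; a condition number above `1e6` raises a
#'   `sl_error_degenerate` error that reports the condition number.
#' @export
pivot_calibrate <- function(poses) {
  if (length(poses) < 3L)
    stop("pivot_calibrate: need >= 3 poses", call. = FALSE)
  n <- length(poses)
  A <- matrix(0, 3 * n, 6)
  rhs <- numeric(3 * n)
  for (i in seq_len(n)) {
    r <- 3 * (i - 1) + 1:3
    A[r, 1:3] <- quat_to_matrix(poses[[i]]$q)
    A[r, 4:6] <- -diag(3)
    rhs[r] <- -poses[[i]]$t
  }
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[6]
  if (!is.finite(cond) || cond > PIVOT_MAX_CONDITION)
    stop(errorCondition(
      sprintf("pivot_calibrate: degenerate pose set (condition number %.3g > %.3g); rotate the tool about more axes",
              cond, PIVOT_MAX_CONDITION),
      class = c("sl_error_degenerate", "error", "condition"),
      condition_number = cond))
  x <- sv$v %*% (crossprod(sv$u, rhs) / sv$d)
  tip <- x[1:3]; pivot <- x[4:6]
  res <- vapply(poses, function(p)
    sqrt(sum((as.numeric(quat_to_matrix(p$q) %*% tip) + p$t - pivot)^2)),
    0)
  structure(list(tip_offset = tip, pivot_point = pivot,
                 rms_residual = sqrt(mean(res^2)),
                 condition_number = cond),
            class = "pivot_result")
}

## 4x4 left/right quaternion multiplication matrices (Hamilton (w,x,y,z)).
quat_left_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w, -x, -y, -z,
           x,  w, -z,  y,
           y,  z,  w, -x,
           z, -y,  x,  w), 4, 4, byrow = TRUE)
}
quat_right_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w, -x, -y, -z,
           x,  w,  z, -y,
           y, -z,  w,  x,
           z,  y, -x,  w), 4, 4, byrow = TRUE)
}

quat_axis <- function(q) {
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) c(0, 0, 0) else q[2:4] / s
}

#' Hand-eye calibration (AX = XB)
#'
#' Solves for the fixed transform `X` between a tracked mount and the camera
#' optical frame from paired relative motions `A_i X = X B_i` (A: mount
#' motion in the tracker, B: camera motion).  Two-step solve: rotation from
#' the stacked linear quaternion system `(L(q_a) - R(q_b)) q_x = 0` by SVD,
#' then translation by least squares of `(R_a - I) t_x = R_x t_b - t_a`.
#'
#' @param motions_a,motions_b equal-length lists of `rigid_transform`
#'   relative motions; at least two pairs with non-parallel rotation axes.
#' @return A `hand_eye_result`: `x` (`rigid_transform`), `rotation_residual`
#'   (rad, rms), `translation_residual` (mm, rms).
#' @export
hand_eye_calibrate <- function(motions_a, motions_b) {
  n <- length(motions_a)
  if (n != length(motions_b))
    stop("hand_eye_calibrate: motion lists differ in length", call. = FALSE)
  if (n < 2L)
    stop(errorCondition("hand_eye_calibrate: need >= 2 motion pairs",
                        class = c("sl_error_underdetermined", "error", "condition")))
  ## axis diversity check on the A motions
  axes <- t(vapply(motions_a, function(m) quat_axis(m$q), numeric(3)))
  ok <- rowSums(axes^2) > 0.5
  if (sum(ok) < 2L)
    stop(errorCondition("hand_eye_calibrate: fewer than 2 non-trivial rotations",
                        class = c("sl_error_underdetermined", "error", "condition")))
  ax <- axes[ok, , drop = FALSE]
  ## max pairwise separation (axes are sign-ambiguous: use |dot|)
  maxsep <- 0
  for (i in seq_len(nrow(ax) - 1))
    for (j in (i + 1):nrow(ax))
      maxsep <- max(maxsep, acos(pmin(1, abs(sum(ax[i, ] * ax[j, ])))))
  if (maxsep < HANDEYE_MIN_AXIS_SEP)
    stop(errorCondition(
      sprintf("hand_eye_calibrate: rotation axes nearly parallel (max separation %.2f deg < %.1f deg)",
              maxsep * 180 / pi, HANDEYE_MIN_AXIS_SEP * 180 / pi),
      class = c("sl_error_underdetermined", "error", "condition")))

  M <- matrix(0, 4 * n, 4)
  for (i in seq_len(n)) {
    qa <- motions_a[[i]]$q; qb <- motions_b[[i]]$q
    ## rotation angles of A and B are equal in theory; align quaternion signs
    if (sum(qa * qb) < 0) qb <- -qb
    M[4 * (i - 1) + 1:4, ] <- quat_left_matrix(qa) - quat_right_matrix(qb)
  }
  sv <- svd(M)
  qx <- sv$v[, 4]
  if (qx[1] < 0) qx <- -qx
  Rx <- quat_to_matrix(qx / sqrt(sum(qx^2)))

  A <- matrix(0, 3 * n, 3); rhs <- numeric(3 * n)
  for (i in seq_len(n)) {
    r <- 3 * (i - 1) + 1:3
    Ra <- quat_to_matrix(motions_a[[i]]$q)
    A[r, ] <- Ra - diag(3)
    rhs[r] <- as.numeric(Rx %*% motions_b[[i]]$t) - motions_a[[i]]$t
  }
  tx <- qr.solve(A, rhs)
  x <- rigid_transform(qx, tx)

  rot_res <- vapply(seq_len(n), function(i) {
    lhs <- rt_compose(motions_a[[i]], x)
    rhs2 <- rt_compose(x, motions_b[[i]])
    rt_rotation_angle(lhs, rhs2)
  }, 0)
  tr_res <- sqrt(mean((A %*% tx - rhs)^2) * 3)
  structure(list(x = x,
                 rotation_residual = sqrt(mean(rot_res^2)),
                 translation_residual = tr_res),
            class = "hand_eye_result")
}

#' Point-based rigid registration (closed form)
#'
#' Least-squares rigid transform mapping `source` onto `target` via the SVD
#' of the cross-covariance (Arun/Umeyama).  A sign correction on the
#' smallest singular direction guards against reflections, so the returned
#' rotation is always proper (det +1).
#'
#' @param source,target N x 3 matrices of corresponding points, mm, N >= 3,
#'   non-collinear.
#' @return A `registration_result`: `transform` (`rigid_transform` mapping
#'   source points to target), `fiducial_registration_error` (rms mm).
#' @export
register_points <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3L, ncol(target) == 3L,
            nrow(source) == nrow(target))
  if (nrow(source) < 3L)
    stop("register_points: need >= 3 correspondences", call. = FALSE)
  cs <- colMeans(source); ct <- colMeans(target)
  X <- sweep(source, 2, cs); Y <- sweep(target, 2, ct)
  sv2 <- svd(X)
  if (sv2$d[2] < 1e-9 * max(sv2$d[1], 1))
    stop(errorCondition("register_points: collinear points, rotation not determined",
                        class = c("sl_error_degenerate", "error", "condition")))
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cs)
  tr <- rigid_transform(matrix_to_quat(R), t)
  fre <- sqrt(mean(rowSums((rt_apply(tr, source) - target)^2)))
  structure(list(transform = tr, fiducial_registration_error = fre),
            class = "registration_result")
}
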