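#' Rigid transform between right-handed coordinate frames
#'
#' A rigid transform holds a proper orthonormal 3x3 rotation and a 3-vector
#' translation (cm) and maps points as `rotation %*% p + translation`. The
#' tracking chain stores the camera extrinsic (marker to camera), the
#' camera-to-marker transforms of the left and right tracking cameras, and
#' the fixed left-to-right stereo transform as objects of this class.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation (cm).
#' @return An object of class `rigid_transform`.
#' @examples
#' Tz <- rigid_transform(rotation_about(c(0, 0, 1), pi / 2))
#' transform_point(Tz, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (cm):", format(round(x$translation, 6)), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param p a length-3 point or a 3-row matrix of points (cm).
#' @return Transformed point(s), same shape as `p`.
#' @export
transform_point <- function(transform, p) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.matrix(p)) {
    stopifnot(nrow(p) == 3L)
    transform$rotation %*% p + transform$translation
  } else {
    as.numeric(transform$rotation %*% p + transform$translation)
  }
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(transform) {
  R <- t(transform$rotation)
  rigid_transform(R, -as.numeric(R %*% transform$translation))
}

#' Compose rigid transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`.
#' @param a,b objects of class `rigid_transform`.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / vnorm(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Left-to-right stereo transform from the two camera-to-marker transforms
#'
#' Both tracking cameras see the same marker: `T_ml` takes left-camera
#' coordinates to marker coordinates and `T_mr` takes right-camera
#' coordinates to marker coordinates. Chaining left -> marker -> right gives
#' the fixed stereo transform `T_rl = T_mr^-1 o T_ml` that maps left-camera
#' coordinates to right-camera coordinates.
#'
#' @param T_ml,T_mr `rigid_transform`s from the left / right camera frame to
#'   the common marker frame.
#' @return The left-to-right `rigid_transform`.
#' @export
relative_camera_transform <- function(T_ml, T_mr) {
  rt_compose(rt_inverse(T_mr), T_ml)
}

# --- quaternion helpers (w-first, right-handed) ---

quat_normalize <- function(q) {
  n <- vnorm(q)
  if (n == 0) stop("zero quaternion")
  q <- q / n
  if (q[1] < 0) q <- -q  # canonical hemisphere for reproducible output
  q
}

#' Convert a rotation matrix to a unit quaternion (w, x, y, z)
#' @param R 3x3 rotation matrix.
#' @return Length-4 unit quaternion, w first, w >= 0.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' Convert a unit quaternion (w, x, y, z) to a rotation matrix
#' @param q length-4 quaternion, w first.
#' @return 3x3 rotation matrix.
#' @export
matrix_from_quat <- function(q) {
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z),     1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
    2 * (x * z + w * y),     2 * (y * z - w * x),     1 - 2 * (x * x + y * y)
  ), 3, 3)
}
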