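#' Pinhole camera intrinsics
#'
#' The intrinsic matrix maps camera coordinates to screen pixels: focal
#' lengths on the diagonal, principal point in the last column.
#'
#' @param fx,fy focal lengths (pixels), strictly positive.
#' @param cx,cy principal point (pixels), inside the image bounds.
#' @param width,height image size (pixels).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width = 640, height = 480) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be strictly positive")
  if (cx < 0 || cx > width || cy < 0 || cy > height)
    stop("principal point must lie inside the image bounds")
  K <- matrix(c(fx, 0, 0, 0, fy, 0, cx, cy, 1), 3, 3)
  structure(list(matrix = K, width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera intrinsics: f = (%g, %g) px, c = (%g, %g) px, %g x %g image\n",
              x$matrix[1, 1], x$matrix[2, 2], x$matrix[1, 3], x$matrix[2, 3],
              x$width, x$height))
  invisible(x)
}

#' Project camera-frame points to screen pixels
#'
#' Perspective division of `K %*% p`: points must have strictly positive
#' depth (in front of the camera).
#'
#' @param K a [camera_intrinsics()].
#' @param p_cam length-3 point or 3-row matrix, camera coordinates (cm).
#' @return Pixel coordinates: length-2 vector or 2-row matrix.
#' @export
project_to_screen <- function(K, p_cam) {
  single <- !is.matrix(p_cam)
  p <- if (single) matrix(p_cam, 3, 1) else p_cam
  stopifnot(nrow(p) == 3L)
  if (any(p[3, ] <= 0)) stop("point behind camera")
  q <- K$matrix %*% p
  px <- q[1:2, , drop = FALSE] / rep(q[3, ], each = 2)
  if (single) as.numeric(px) else px
}

#' A (possibly missed) square-marker detection in one camera frame
#'
#' @param corners 4x2 matrix of ordered corner pixels, or `NULL` when the
#'   marker was not detected in this frame.
#' @param camera_id `"left"` or `"right"`.
#' @param time frame time (s).
#' @return An object of class `marker_observation`.
#' @export
marker_observation <- function(corners = NULL, camera_id = c("left", "right"),
                               time = 0) {
  camera_id <- match.arg(camera_id)
  if (!is.null(corners)) {
    corners <- matrix(as.numeric(corners), ncol = 2)
    if (nrow(corners) != 4L) stop("a marker observation needs 4 corners")
  }
  structure(list(corners = corners, camera_id = camera_id, time = time),
            class = "marker_observation")
}

#' Canonical marker corners
#'
#' Corners of the square fiducial in marker coordinates (z = 0 plane),
#' counter-clockwise starting top-left.
#'
#' @param side marker side length (cm).
#' @return 4x3 matrix of corner coordinates.
#' @export
marker_corners <- function(side) {
  s <- side / 2
  matrix(c(-s,  s, 0,
           -s, -s, 0,
            s, -s, 0,
            s,  s, 0), 4, 3, byrow = TRUE)
}

# Direct linear transform homography from 4 planar correspondences.
# src: 4x2 marker-plane coords, dst: 4x2 pixels. Returns 3x3 H.
dlt_homography <- function(src, dst) {
  A <- matrix(0, 8, 9)
  for (k in 1:4) {
    X <- src[k, 1]; Y <- src[k, 2]
    u <- dst[k, 1]; v <- dst[k, 2]
    A[2 * k - 1, ] <- c(-X, -Y, -1, 0, 0, 0, u * X, u * Y, u)
    A[2 * k, ]     <- c(0, 0, 0, -X, -Y, -1, v * X, v * Y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1]) stop("pose unrecoverable: degenerate corners")
  matrix(sv$v[, 9], 3, 3, byrow = TRUE)
}

#' Recover the marker pose from one square-marker observation
#'
#' Estimates the camera extrinsic (marker frame to camera frame) from the
#' four imaged corners of a known-size square: a planar homography is fit by
#' direct linear transform, decomposed against the intrinsics, and the
#' rotation re-orthonormalized by SVD.
#'
#' @param K a [camera_intrinsics()].
#' @param obs a [marker_observation()] with 4 detected corners, ordered as
#'   [marker_corners()].
#' @param side_length marker side (cm).
#' @return A [rigid_transform()] mapping marker coordinates to camera
#'   coordinates.
#' @export
estimate_pose_from_square <- function(K, obs, side_length) {
  if (is.null(obs$corners)) stop("marker not detected: no corners")
  corners <- obs$corners
  # collinearity / degeneracy guard: area of the quadrilateral
  a <- abs(sum(corners[, 1] * corners[c(2:4, 1), 2] -
               corners[c(2:4, 1), 1] * corners[, 2])) / 2
  if (a < 1e-8) stop("pose unrecoverable: degenerate corners")
  src <- marker_corners(side_length)[, 1:2]
  H <- dlt_homography(src, corners)
  M <- solve(K$matrix, H)
  s <- 2 / (vnorm(M[, 1]) + vnorm(M[, 2]))
  if ((s * M[3, 3]) < 0) s <- -s  # marker must be in front of the camera
  r1 <- s * M[, 1]; r2 <- s * M[, 2]
  R0 <- cbind(r1, r2, cross3(r1, r2))
  sv <- svd(R0)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  rigid_transform(R, s * M[, 3])
}

#' Synthesize a marker observation from a known pose
#'
#' Projects the canonical marker corners through `K` and the given extrinsic;
#' the inverse operation of [estimate_pose_from_square()]. Corners falling
#' outside the image mark the frame as a missed detection (`corners = NULL`).
#'
#' @param K a [camera_intrinsics()].
#' @param pose marker-to-camera [rigid_transform()].
#' @param side_length marker side (cm).
#' @param camera_id,time observation metadata.
#' @param noise_px optional Gaussian pixel noise SD added to the corners.
#' @return A [marker_observation()].
#' @export
project_marker <- function(K, pose, side_length, camera_id = "left",
                           time = 0, noise_px = 0) {
  corners3 <- t(marker_corners(side_length))
  cam <- transform_point(pose, corners3)
  if (any(cam[3, ] <= 0)) return(marker_observation(NULL, camera_id, time))
  px <- t(project_to_screen(K, cam))
  if (noise_px > 0) px <- px + matrix(stats::rnorm(8, sd = noise_px), 4, 2)
  inside <- all(px[, 1] >= 0 & px[, 1] <= K$width &
                px[, 2] >= 0 & px[, 2] <= K$height)
  if (!inside) return(marker_observation(NULL, camera_id, time))
  marker_observation(px, camera_id, time)
}

#' Stereo tracking rig
#'
#' @param K_l,K_r intrinsics of the left and right tracking cameras.
#' @param T_rl [rigid_transform()] mapping left-camera coordinates to
#'   right-camera coordinates.
#' @param side_length marker side (cm).
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(K_l, K_r, T_rl, side_length) {
  stopifnot(inherits(K_l, "camera_intrinsics"),
            inherits(K_r, "camera_intrinsics"),
            inherits(T_rl, "rigid_transform"), side_length > 0)
  structure(list(K_l = K_l, K_r = K_r, T_rl = T_rl,
                 side_length = side_length), class = "stereo_rig")
}

#' Resolve one tracked sample from a stereo frame pair
#'
#' Implements the per-frame fallback: use the left camera when it sees the
#' marker; otherwise use the right camera and map its pose into the
#' left-camera convention through the stereo transform; otherwise repeat the
#' previous pose (`source = "held"`). The returned pose is the marker frame
#' expressed in left-camera coordinates.
#'
#' @param left,right [marker_observation()]s for the frame (corners `NULL`
#'   when missed); either may be `NULL`.
#' @param prev previous tracked sample (one-row `trajectory`) or `NULL`.
#' @param rig a [stereo_rig()].
#' @param time frame time (s); defaults to the left observation's time.
#' @return A one-row `trajectory`.
#' @export
resolve_marker_pose <- function(left, right, prev, rig,
                                time = NULL) {
  time <- time %||% (if (!is.null(left)) left$time else
                     if (!is.null(right)) right$time else
                     if (!is.null(prev)) prev$time[1] + 1 / 30 else NULL)
  if (is.null(time)) stop("no pose available: no observations and no previous sample")
  if (!is.null(left) && !is.null(left$corners)) {
    pose <- estimate_pose_from_square(rig$K_l, left, rig$side_length)
    src <- "left"
  } else if (!is.null(right) && !is.null(right$corners)) {
    pose_r <- estimate_pose_from_square(rig$K_r, right, rig$side_length)
    pose <- rt_compose(rt_inverse(rig$T_rl), pose_r)
    src <- "right"
  } else if (!is.null(prev)) {
    return(trajectory(time,
                      matrix(c(prev$x[1], prev$y[1], prev$z[1]), 1),
                      matrix(c(prev$qw[1], prev$qx[1], prev$qy[1], prev$qz[1]), 1),
                      source = "held"))
  } else {
    stop("no pose available: marker missed in both cameras and no previous sample")
  }
  trajectory(time, matrix(pose$translation, 1),
             matrix(quat_from_matrix(pose$rotation), 1), source = src)
}

#' Resolve a whole stereo sequence into a trajectory
#'
#' @param lefts,rights lists of [marker_observation()]s, same length.
#' @param rig a [stereo_rig()].
#' @return A `trajectory` with one row per frame.
#' @export
track_sequence <- function(lefts, rights, rig) {
  stopifnot(length(lefts) == length(rights), length(lefts) >= 1)
  rows <- vector("list", length(lefts))
  prev <- NULL
  for (i in seq_along(lefts)) {
    prev <- resolve_marker_pose(lefts[[i]], rights[[i]], prev, rig)
    rows[[i]] <- prev
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  as_trajectory(out)
}
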