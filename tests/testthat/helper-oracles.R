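# Independent oracles and generators used across the suite. These never call
# the package's own basis/evaluation code paths.

# Literal recursive Cox-de Boor basis (zero-based index). Valid for u in
# [0, 1); the half-open degree-0 indicator is taken as printed.
oracle_basis <- function(i, p, U, u) {
  if (p == 0) return(as.numeric(U[i + 1] <= u && u < U[i + 2]))
  d1 <- U[i + p + 1] - U[i + 1]
  d2 <- U[i + p + 2] - U[i + 2]
  t1 <- if (d1 > 0) (u - U[i + 1]) / d1 * oracle_basis(i, p - 1, U, u) else 0
  t2 <- if (d2 > 0) (U[i + p + 2] - u) / d2 * oracle_basis(i + 1, p - 1, U, u) else 0
  t1 + t2
}

# Curve evaluation through splines::splineDesign (independent compiled
# implementation) on homogeneous coordinates.
oracle_eval <- function(curve, u) {
  N <- splines::splineDesign(curve$knots, u, ord = curve$degree + 1)
  Nw <- N * rep(curve$weights, each = length(u))
  (Nw %*% curve$control_points) / rowSums(Nw)
}

# Brute-force closest point by dense parameter scan.
oracle_closest <- function(curve, x, n = 1e5) {
  g <- seq(0, 1, length.out = n)
  pts <- evaluate_curve(curve, g)
  d <- sqrt((pts[, 1] - x[1])^2 + (pts[, 2] - x[2])^2 + (pts[, 3] - x[3])^2)
  i <- which.min(d)
  list(u = g[i], distance = d[i])
}

# Random valid NURBS curve (possibly non-unit weights, random interior knots).
random_curve <- function(seed, degree = NULL, m = NULL) {
  set.seed(seed)
  p <- degree %||% sample(2:4, 1)
  m <- m %||% sample((p + 2):12, 1)
  n_int <- m - p - 1
  interior <- if (n_int > 0) sort(runif(n_int, 0.05, 0.95)) else numeric(0)
  while (n_int > 0 && any(diff(c(0, interior, 1)) < 1e-3)) {
    interior <- sort(runif(n_int, 0.05, 0.95))
  }
  U <- c(rep(0, p + 1), interior, rep(1, p + 1))
  arthroguide:::new_nurbs_curve(p, U, matrix(rnorm(3 * m, sd = 3), m, 3),
                                runif(m, 0.5, 2), 0, 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random proper rigid transform.
random_transform <- function(seed = NULL, max_translation = 10) {
  if (!is.null(seed)) set.seed(seed)
  ax <- rnorm(3)
  rigid_transform(rotation_about(ax, runif(1, 0, pi)),
                  runif(3, -max_translation, max_translation))
}

# Straight-line trajectory fixture from `a` to `b`.
line_trajectory <- function(a, b, n = 20, t_end = 1) {
  s <- seq(0, 1, length.out = n)
  trajectory(seq(0, t_end, length.out = n),
             cbind(a[1] + s * (b[1] - a[1]),
                   a[2] + s * (b[2] - a[2]),
                   a[3] + s * (b[3] - a[3])))
}

# A synthetic converged stereo rig: right camera 8 cm to the right of the
# left one, toed in toward the working volume centre (0, 0, 30).
test_rig <- function(side = 4) {
  K_l <- camera_intrinsics(800, 800, 320, 240, 640, 480)
  K_r <- camera_intrinsics(780, 790, 330, 235, 640, 480)
  R <- rotation_about(c(0, 1, 0), atan2(8, 30))
  T_rl <- rigid_transform(R, -as.numeric(R %*% c(8, 0, 0)))
  stereo_rig(K_l, K_r, T_rl, side)
}

# Random marker pose visible from both test cameras: off-axis rotation up to
# 60 degrees, centred in the shared working volume.
random_marker_pose <- function(depth = NULL) {
  ax <- rnorm(3)
  ang <- runif(1, 0, pi / 3)
  depth <- depth %||% runif(1, 18, 45)
  rigid_transform(rotation_about(ax, ang),
                  c(runif(1, -2, 2), runif(1, -2, 2), depth))
}
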