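#' Fit a smoothing/compressing NURBS curve to a tracked trajectory
#'
#' The central model of the package: a degree-`p` NURBS curve with `m`
#' weighted control points is fit by linear least squares to the `n > m`
#' tracked positions of an expert inspection trajectory, parameterized by
#' normalized recording time. The first and last control points are pinned
#' to the first and last data points, so the smoothed curve starts and ends
#' exactly where the recording did; the interior control points minimize the
#' sum of squared residuals. The fit simultaneously filters tracking noise
#' and compresses the recording from `n` samples to `m` control points.
#'
#' Orientation quaternions are not spline-fitted; the curve models positions
#' only, and the recorded time window `[t0, t1]` is carried along so that
#' curve parameters map back to recording time (see [map_time()]).
#'
#' @param traj a `trajectory` (or data frame with `time`, `x`, `y`, `z`).
#' @param n_control number of control points `m`, with
#'   `degree + 1 <= m < n`.
#' @param degree spline degree `p` (default cubic).
#' @param weights positive control-point weights, length `m` or scalar
#'   (default all 1: the rational curve reduces to a B-spline).
#' @return An object of class `nurbs_curve` with components `degree`,
#'   `knots`, `control_points` (m x 3), `weights`, `t0`, `t1`, plus the
#'   fitting data, fitted values and residuals.
#' @seealso [predict.nurbs_curve()], [closest_point()],
#'   [simulate.nurbs_curve()], [normal_path_error()]
#' @examples
#' tr <- generate_expert_trajectory(expert_path_params(duration = 5, seed = 1))
#' fit <- nurbs_fit(tr, n_control = 10)
#' fit
#' predict(fit, u = c(0, 0.5, 1))
#' @export
nurbs_fit <- function(traj, n_control, degree = 3, weights = NULL) {
  Q <- as.matrix(as.data.frame(traj)[c("x", "y", "z")])
  n <- nrow(Q)
  m <- as.integer(n_control)
  p <- as.integer(degree)
  if (p < 1) stop("degree must be at least 1")
  if (m < p + 1) stop("too few control points")
  if (m >= n) stop("no compression: need fewer control points than samples (m < n)")
  w <- if (is.null(weights)) rep(1, m) else rep_len(as.numeric(weights), m)
  if (any(w <= 0)) stop("invalid weight")

  ubar <- time_parameterize(traj)
  U <- build_knot_vector(p, m, ubar)
  Nw <- basis_matrix(U, p, ubar) * rep(w, each = n)
  Rb <- Nw / rowSums(Nw)

  # pinned endpoints: P[1] = Q[1], P[m] = Q[n]; interior by least squares
  P <- matrix(0, m, 3)
  P[1, ] <- Q[1, ]
  P[m, ] <- Q[n, ]
  if (m > 2) {
    A <- Rb[, 2:(m - 1), drop = FALSE]
    rhs <- Q - outer(Rb[, 1], P[1, ]) - outer(Rb[, m], P[m, ])
    qrA <- qr(A)
    if (qrA$rank < m - 2)
      stop("ill-conditioned fit: rank-deficient basis matrix")
    P[2:(m - 1), ] <- qr.coef(qrA, rhs)
  }

  curve <- new_nurbs_curve(p, U, P, w, traj$time[1], traj$time[n])
  fitted <- Rb %*% P
  curve$data <- as.data.frame(traj)
  curve$ubar <- ubar
  curve$fitted.values <- fitted
  curve$residuals <- Q - fitted
  curve$call <- match.call()
  curve
}

# Low-level constructor + invariant checks; also builds the dense parameter
# grid cached for closest-point searches.
new_nurbs_curve <- function(degree, knots, control_points, weights, t0, t1,
                            grid_n = 512) {
  p <- as.integer(degree)
  m <- nrow(control_points)
  if (length(knots) != m + p + 1) stop("knot count must equal m + p + 1")
  if (any(diff(knots) < 0)) stop("knots must be non-decreasing")
  if (any(knots[seq_len(p + 1)] != knots[1]) ||
      any(knots[(m + 1):(m + p + 1)] != knots[m + p + 1]))
    stop("knot vector must be clamped (p + 1 repeated end knots)")
  if (length(weights) != m || any(weights <= 0)) stop("invalid weight")
  curve <- structure(list(degree = p, knots = as.numeric(knots),
                          control_points = control_points,
                          weights = as.numeric(weights),
                          t0 = t0, t1 = t1), class = "nurbs_curve")
  g <- seq(0, 1, length.out = grid_n)
  curve$grid_u <- g
  curve$grid_pts <- evaluate_curve(curve, g)
  curve
}

#' Evaluate a NURBS curve
#'
#' Computes `C(u) = sum_i R[i,p](u) P_i` at the given parameters. No
#' extrapolation: `u` must lie in `[0, 1]`.
#'
#' @param curve a `nurbs_curve`.
#' @param u parameter value(s) in `[0, 1]`.
#' @return `length(u)` x 3 matrix of positions (cm).
#' @export
evaluate_curve <- function(curve, u) {
  if (any(u < 0 | u > 1)) stop("parameter out of range [0, 1]")
  Nw <- basis_matrix(curve$knots, curve$degree, u) *
    rep(curve$weights, each = length(u))
  (Nw / rowSums(Nw)) %*% curve$control_points
}

# Value + first two derivatives of the curve w.r.t. u (quotient rule on the
# homogeneous form A(u)/W(u)). Returns list of length(u) x 3 matrices.
curve_derivs <- function(curve, u) {
  w <- curve$weights
  P <- curve$control_points
  wl <- rep(w, each = length(u))
  N0 <- basis_matrix(curve$knots, curve$degree, u) * wl
  N1 <- basis_matrix_deriv(curve$knots, curve$degree, u) * wl
  N2 <- basis_matrix_deriv2(curve$knots, curve$degree, u) * wl
  W0 <- rowSums(N0); W1 <- rowSums(N1); W2 <- rowSums(N2)
  A0 <- N0 %*% P; A1 <- N1 %*% P; A2 <- N2 %*% P
  C0 <- A0 / W0
  C1 <- (A1 - C0 * W1) / W0
  C2 <- (A2 - 2 * C1 * W1 - C0 * W2) / W0
  list(C = C0, C1 = C1, C2 = C2)
}

#' Map a curve parameter back to recording time
#'
#' `t = t0 + u (t1 - t0)`: the linear change of variable between the
#' normalized curve parameter and the recorded clock of the expert session.
#'
#' @param curve a `nurbs_curve`.
#' @param u parameter(s) in `[0, 1]`.
#' @return Time(s) in seconds.
#' @export
map_time <- function(curve, u) {
  curve$t0 + u * (curve$t1 - curve$t0)
}

#' Inverse of [map_time()]
#' @param curve a `nurbs_curve`.
#' @param t time(s) in seconds, clamped to the curve's window.
#' @return Parameter(s) in `[0, 1]`.
#' @export
time_to_param <- function(curve, t) {
  if (curve$t1 == curve$t0) stop("degenerate time window")
  clamp((t - curve$t0) / (curve$t1 - curve$t0), 0, 1)
}

#' Closest point on a NURBS curve
#'
#' Orthogonal projection of a point onto the curve: a coarse scan over a
#' dense cached parameter grid brackets the minimizer, then Brent refinement
#' (tolerance 1e-10 in `u`) polishes it. Ties are broken toward the smallest
#' parameter.
#'
#' @param curve a `nurbs_curve`.
#' @param x length-3 point (cm).
#' @return A list with `u` (minimizing parameter), `point` (3-vector on the
#'   curve) and `distance` (cm).
#' @export
closest_point <- function(curve, x) {
  x <- as.numeric(x)
  d2 <- (curve$grid_pts[, 1] - x[1])^2 + (curve$grid_pts[, 2] - x[2])^2 +
        (curve$grid_pts[, 3] - x[3])^2
  i <- which.min(d2)
  g <- curve$grid_u
  lo <- g[max(1L, i - 1L)]; hi <- g[min(length(g), i + 1L)]
  f <- function(u) sum((evaluate_curve(curve, u) - x)^2)
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
  cand_u <- c(opt$minimum, lo, hi)
  cand_f <- c(opt$objective, f(lo), f(hi))
  u <- cand_u[which.min(cand_f)]
  pt <- as.numeric(evaluate_curve(curve, u))
  list(u = u, point = pt, distance = vnorm(pt - x))
}

# Vectorised closest-point distances for many query points: grid bracket
# followed by a safeguarded Newton iteration on the squared-distance
# derivative, all evaluated batch-wise.
closest_point_batch <- function(curve, X, iters = 12) {
  X <- matrix(as.numeric(X), ncol = 3)
  G <- curve$grid_pts
  n <- nrow(X)
  # pairwise squared distances (n queries x grid)
  d2 <- outer(rowSums(X^2), rowSums(G^2), "+") - 2 * X %*% t(G)
  idx <- max.col(-d2, ties.method = "first")
  u <- curve$grid_u[idx]
  best_u <- u
  best_d2 <- d2[cbind(seq_len(n), idx)]
  step0 <- diff(curve$grid_u[1:2])
  for (k in seq_len(iters)) {
    dv <- curve_derivs(curve, u)
    E <- dv$C - X
    g1 <- 2 * rowSums(E * dv$C1)
    g2 <- 2 * (rowSums(dv$C1^2) + rowSums(E * dv$C2))
    step <- ifelse(g2 > 1e-12, -g1 / g2, 0)
    step <- clamp(step, -step0, step0)
    u <- clamp(u + step, 0, 1)
    cur_d2 <- rowSums((evaluate_curve(curve, u) - X)^2)
    better <- cur_d2 < best_d2
    best_u[better] <- u[better]
    best_d2[better] <- cur_d2[better]
    u <- best_u
  }
  list(u = best_u, distance = sqrt(pmax(best_d2, 0)))
}
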