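#' B-spline basis function (Cox-de Boor recursion)
#'
#' Evaluates the degree-`p` B-spline basis function `N[i,p]` on a clamped
#' knot vector, with 0/0 terms treated as 0 and the curve domain closed at
#' the right end (`u = 1` belongs to the last non-empty span).
#'
#' @param i zero-based basis index, `0 <= i <= m - 1` where
#'   `m = length(U) - p - 1`.
#' @param p degree (non-negative integer).
#' @param U non-decreasing knot vector in `[0, 1]`.
#' @param u parameter value(s) in `[0, 1]`.
#' @return Numeric vector of basis values, one per element of `u`.
#' @export
bspline_basis <- function(i, p, U, u) {
  m <- length(U) - p - 1
  if (length(i) != 1 || i < 0 || i > m - 1)
    stop("basis index out of range")
  basis_matrix(U, p, u)[, i + 1]
}

# Full basis matrix: length(u) x (length(U) - p - 1), iterative Cox-de Boor.
basis_matrix <- function(U, p, u) {
  u <- as.numeric(u)
  nk <- length(U)
  nb <- nk - 1L
  B <- matrix(0, length(u), nb)
  for (j in seq_len(nb))
    if (U[j + 1] > U[j]) B[, j] <- as.numeric(u >= U[j] & u < U[j + 1])
  # close the domain at the maximal knot
  spans <- which(diff(U) > 0)
  if (length(spans)) B[u == U[nk], spans[length(spans)]] <- 1
  if (p == 0) return(B)
  for (d in seq_len(p)) {
    nb <- nb - 1L
    Bn <- matrix(0, length(u), nb)
    for (j in seq_len(nb)) {
      den1 <- U[j + d] - U[j]
      den2 <- U[j + d + 1] - U[j + 1]
      t1 <- if (den1 > 0) (u - U[j]) / den1 * B[, j] else 0
      t2 <- if (den2 > 0) (U[j + d + 1] - u) / den2 * B[, j + 1] else 0
      Bn[, j] <- t1 + t2
    }
    B <- Bn
  }
  B
}

# First-derivative basis matrix d/du N[i,p](u).
basis_matrix_deriv <- function(U, p, u) {
  m <- length(U) - p - 1
  if (p == 0) return(matrix(0, length(u), m))
  Blow <- basis_matrix(U, p - 1, u)           # columns: N[i, p-1]
  D <- matrix(0, length(u), m)
  for (i in seq_len(m)) {
    den1 <- U[i + p] - U[i]
    den2 <- U[i + p + 1] - U[i + 1]
    t1 <- if (den1 > 0) p / den1 * Blow[, i] else 0
    t2 <- if (den2 > 0) p / den2 * Blow[, i + 1] else 0
    D[, i] <- t1 - t2
  }
  D
}

# Second-derivative basis matrix.
basis_matrix_deriv2 <- function(U, p, u) {
  m <- length(U) - p - 1
  if (p <= 1) return(matrix(0, length(u), m))
  Dlow <- basis_matrix_deriv(U, p - 1, u)
  D <- matrix(0, length(u), m)
  for (i in seq_len(m)) {
    den1 <- U[i + p] - U[i]
    den2 <- U[i + p + 1] - U[i + 1]
    t1 <- if (den1 > 0) p / den1 * Dlow[, i] else 0
    t2 <- if (den2 > 0) p / den2 * Dlow[, i + 1] else 0
    D[, i] <- t1 - t2
  }
  D
}

#' Rational basis function
#'
#' The weighted, normalized counterpart of [bspline_basis()]:
#' `R[i,p](u) = N[i,p](u) w_i / sum_j N[j,p](u) w_j`.
#'
#' @inheritParams bspline_basis
#' @param weights positive weight per control point.
#' @return Numeric vector of rational basis values.
#' @export
rational_basis <- function(i, p, U, weights, u) {
  m <- length(U) - p - 1
  if (length(i) != 1 || i < 0 || i > m - 1)
    stop("basis index out of range")
  if (length(weights) != m || any(weights <= 0)) stop("invalid weight")
  Nw <- basis_matrix(U, p, u) * rep(weights, each = length(u))
  Nw[, i + 1] / rowSums(Nw)
}

#' Normalized time parameterization of a trajectory
#'
#' Maps sample times linearly onto `[0, 1]`:
#' `u_i = (t_i - t0) / (t1 - t0)`.
#'
#' @param traj a `trajectory` (or data frame with a `time` column), n >= 2,
#'   strictly increasing times.
#' @return Numeric vector of parameters with first element 0, last 1.
#' @export
time_parameterize <- function(traj) {
  t <- traj$time
  if (length(t) < 2) stop("need at least two samples")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  t0 <- t[1]; t1 <- t[length(t)]
  if (t1 == t0) stop("degenerate time window")
  u <- (t - t0) / (t1 - t0)
  u[1] <- 0; u[length(u)] <- 1
  u
}

#' Clamped knot vector for least-squares fitting
#'
#' Builds the non-periodic knot vector with `p + 1` zeros, `m - p - 1`
#' strictly increasing interior knots, and `p + 1` ones. Interior knots are
#' placed by the averaging rule applied to the data parameters resampled at
#' `m` positions, which keeps the fitting matrix well conditioned.
#'
#' @param p degree.
#' @param m number of control points (`m > p`).
#' @param ubar sorted data parameters in `[0, 1]`.
#' @return Knot vector of length `m + p + 1`.
#' @export
build_knot_vector <- function(p, m, ubar) {
  if (m <= p) stop("too few control points")
  n_int <- m - p - 1
  if (n_int == 0) return(c(rep(0, p + 1), rep(1, p + 1)))
  n <- length(ubar)
  ub <- if (n == m) ubar else
    stats::approx(seq_len(n), ubar, xout = seq(1, n, length.out = m))$y
  interior <- vapply(seq_len(n_int),
                     function(j) mean(ub[(j + 1):(j + p)]), numeric(1))
  if (any(diff(c(0, interior, 1)) <= 0))
    stop("degenerate parameterization: interior knots not increasing")
  c(rep(0, p + 1), interior, rep(1, p + 1))
}
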