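test_that("a cubic fit reproduces straight-line data to machine precision", {
  tr <- line_trajectory(c(0, 0, 0), c(10, 5, -2), n = 20)
  fit <- nurbs_fit(tr, n_control = 4, degree = 3)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_identical(coef(fit)[1, ], c(x = 0, y = 0, z = 0))
  expect_identical(unname(coef(fit)[4, ]), c(10, 5, -2))
})

test_that("endpoints are pinned and interpolated by the clamped curve", {
  set.seed(9)
  tr <- generate_expert_trajectory(expert_path_params(duration = 6, seed = 9))
  fit <- nurbs_fit(tr, n_control = 9)
  Q <- as.matrix(as.data.frame(tr)[c("x", "y", "z")])
  expect_identical(unname(coef(fit)[1, ]), unname(Q[1, ]))
  expect_identical(unname(coef(fit)[9, ]), unname(Q[nrow(Q), ]))
  # clamped endpoint interpolation C(0) = P_0, C(1) = P_m-1
  expect_equal(as.numeric(evaluate_curve(fit, 0)), unname(coef(fit)[1, ]),
               tolerance = 1e-12)
  expect_equal(as.numeric(evaluate_curve(fit, 1)), unname(coef(fit)[9, ]),
               tolerance = 1e-12)
})

test_that("a circular arc is approximated to a fraction of its radius", {
  radius <- 5
  th <- seq(0, pi, length.out = 100)
  tr <- trajectory(seq(0, 10, length.out = 100),
                   cbind(radius * cos(th), radius * sin(th), 0.3 * th))
  fit <- nurbs_fit(tr, n_control = 12, degree = 3)
  expect_lt(max(sqrt(rowSums(residuals(fit)^2))), 1e-3 * radius)

  # cross-check the interior solve against explicit normal equations
  ubar <- time_parameterize(tr)
  U <- fit$knots
  B <- arthroguide:::basis_matrix(U, 3, ubar)  # unit weights: rational = plain
  Q <- as.matrix(as.data.frame(tr)[c("x", "y", "z")])
  A <- B[, 2:11]
  rhs <- Q - outer(B[, 1], Q[1, ]) - outer(B[, 12], Q[100, ])
  P_int <- solve(crossprod(A), crossprod(A, rhs))
  expect_equal(unname(coef(fit)[2:11, ]), unname(P_int), tolerance = 1e-8)
})

test_that("residual RMS tracks the injected noise level", {
  sigma <- 0.1
  rms <- numeric(20)
  for (s in 1:20) {
    set.seed(700 + s)
    th <- seq(0, 2, length.out = 200)
    pos <- cbind(5 * cos(th), 5 * sin(th), th) +
      matrix(rnorm(600, sd = sigma), 200, 3)
    tr <- trajectory(seq(0, 10, length.out = 200), pos)
    fit <- nurbs_fit(tr, n_control = 10)
    rms[s] <- sqrt(mean(rowSums(residuals(fit)^2) / 3))
  }
  expect_true(all(rms > 0.5 * sigma & rms < 1.5 * sigma))
})

test_that("fitting smooths: the curve's discrete curvature is below the raw polyline's", {
  for (s in 1:20) {
    set.seed(800 + s)
    tr <- generate_expert_trajectory(expert_path_params(duration = 5, seed = s))
    noisy <- add_tracking_noise(tr, tracker_noise_params(sigma = 0.08, dropout_prob = 0,
                                                         seed = 900 + s))
    fit <- nurbs_fit(noisy, n_control = 10)
    ubar <- time_parameterize(noisy)
    raw <- as.matrix(as.data.frame(noisy)[c("x", "y", "z")])
    smooth <- evaluate_curve(fit, ubar)
    total_curv <- function(P) sum(sqrt(rowSums(diff(diff(P))^2)))
    expect_lt(total_curv(smooth), total_curv(raw))
  }
})

test_that("degenerate fitting requests are rejected", {
  tr <- line_trajectory(c(0, 0, 0), c(1, 0, 0), n = 10)
  expect_error(nurbs_fit(tr, n_control = 10), "no compression")
  expect_error(nurbs_fit(tr, n_control = 12), "no compression")
  expect_error(nurbs_fit(tr, n_control = 3, degree = 3), "too few control points")
})

test_that("constant control polygons and collinear points evaluate exactly", {
  # all control points equal: C(u) = P everywhere (partition of unity)
  cvP <- arthroguide:::new_nurbs_curve(3, c(0, 0, 0, 0, 0.5, 1, 1, 1, 1),
                                       matrix(rep(c(2, -1, 4), each = 5), 5, 3),
                                       rep(1, 5), 0, 1)
  for (u in c(0, 0.2, 0.77, 1)) {
    expect_equal(as.numeric(evaluate_curve(cvP, u)), c(2, -1, 4),
                 tolerance = 1e-12)
  }

  # single-span quadratic through collinear control points: midpoint at u = 0.5
  cvL <- arthroguide:::new_nurbs_curve(2, c(0, 0, 0, 1, 1, 1),
                                       rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                       rep(1, 3), 0, 1)
  expect_equal(as.numeric(evaluate_curve(cvL, 0.5)), c(1, 0, 0),
               tolerance = 1e-14)
  expect_error(evaluate_curve(cvL, 1.2), "out of range")
})

test_that("evaluation agrees with an independent spline implementation", {
  for (s in 1:20) {
    cv <- random_curve(seed = 400 + s)
    u <- seq(0, 1, length.out = 101)
    expect_lt(max(abs(evaluate_curve(cv, u) - oracle_eval(cv, u))), 1e-10)
  }
})

test_that("map_time is the linear clock of the recording window", {
  tr <- line_trajectory(c(0, 0, 0), c(1, 1, 1), n = 12, t_end = 10)
  tr$time <- tr$time + 2  # window [2, 12]
  fit <- nurbs_fit(as_trajectory(tr), n_control = 4)
  expect_equal(map_time(fit, 0), 2)
  expect_equal(map_time(fit, 1), 12)
  expect_equal(map_time(fit, 0.3), 5)
  u <- seq(0, 1, length.out = 50)
  expect_true(all(diff(map_time(fit, u)) > 0))
  expect_equal(time_to_param(fit, 5), 0.3)
})

test_that("closest-point projection matches analytic and brute-force answers", {
  seg <- nurbs_fit(line_trajectory(c(0, 0, 0), c(10, 0, 0), n = 20),
                   n_control = 4)
  cp <- closest_point(seg, c(3, 4, 0))
  expect_equal(cp$point, c(3, 0, 0), tolerance = 1e-6)
  expect_equal(cp$distance, 4, tolerance = 1e-8)
  expect_equal(cp$u, 0.3, tolerance = 1e-3)

  # self-projection
  on_curve <- as.numeric(evaluate_curve(seg, 0.42))
  expect_lt(closest_point(seg, on_curve)$distance, 1e-8)

  # dense-scan oracle on random curves, scalar and batch paths
  set.seed(31)
  for (s in 1:5) {
    cv <- random_curve(seed = 500 + s)
    X <- matrix(rnorm(15, sd = 4), 5, 3)
    batch <- arthroguide:::closest_point_batch(cv, X)
    for (i in 1:5) {
      ref <- oracle_closest(cv, X[i, ])
      cp <- closest_point(cv, X[i, ])
      expect_lt(abs(cp$distance - ref$distance), 1e-4)
      expect_lt(abs(batch$distance[i] - ref$distance), 1e-4)
    }
  }
})

test_that("curve serialization round-trips exactly and compresses the recording", {
  tr <- generate_expert_trajectory(expert_path_params(duration = 10, seed = 17))
  noisy <- add_tracking_noise(tr, tracker_noise_params(seed = 18))
  fit <- nurbs_fit(noisy, n_control = 12)

  path <- tempfile(fileext = ".json")
  write_curve_json(fit, path)
  back <- read_curve_json(path)
  expect_identical(back$knots, fit$knots)
  expect_identical(unname(back$control_points), unname(fit$control_points))
  expect_identical(back$weights, fit$weights)
  expect_identical(c(back$t0, back$t1), c(fit$t0, fit$t1))

  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(noisy, csv)
  expect_lt(file.size(path), file.size(csv))  # m = 12 << n/2 = 150
})
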