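test_that("attractive force has the three printed regimes", {
  cfg <- guidance_config(k_A = 2, d_A = 0.5, d_t = 0.1)
  D <- c(0, 0, 0)
  # far: saturated at magnitude k_A * d_A
  expect_equal(attractive_force(c(10, 0, 0), D, cfg), c(1, 0, 0))
  # linear band
  expect_equal(attractive_force(c(0.3, 0, 0), D, cfg), c(0.6, 0, 0))
  # dead zone
  expect_identical(attractive_force(c(0.05, 0, 0), D, cfg), c(0, 0, 0))
  # coincident probe and anchor
  expect_identical(attractive_force(D, D, cfg), c(0, 0, 0))
})

test_that("attractive force is continuous at d_A and bounded by k_A * d_A", {
  set.seed(77)
  for (k in 1:20) {
    cfg <- guidance_config(k_A = runif(1, 0.5, 10), d_A = runif(1, 0.5, 3),
                           d_t = runif(1, 0.01, 0.3))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    f_out <- attractive_force(cfg$d_A * (1 + 1e-13) * dir, c(0, 0, 0), cfg)
    f_in <- attractive_force(cfg$d_A * (1 - 1e-13) * dir, c(0, 0, 0), cfg)
    expect_lt(max(abs(f_out - f_in)), 1e-12 * cfg$k_A * cfg$d_A + 1e-12)
    expect_equal(sqrt(sum(f_out^2)), cfg$k_A * cfg$d_A, tolerance = 1e-9)
    # saturation everywhere
    for (r in c(0.05, 0.5, 1, 5, 100)) {
      f <- attractive_force(r * dir, c(0, 0, 0), cfg)
      expect_lte(sqrt(sum(f^2)), cfg$k_A * cfg$d_A * (1 + 1e-12))
    }
  }
})

test_that("optional smooth dead zone ramps linearly to zero", {
  cfg <- guidance_config(k_A = 2, d_A = 0.5, d_t = 0.1, smooth_dead_zone = TRUE)
  # continuous at d_t
  f_out <- attractive_force(c(0.1 + 1e-13, 0, 0), c(0, 0, 0), cfg)
  f_in <- attractive_force(c(0.1 - 1e-13, 0, 0), c(0, 0, 0), cfg)
  expect_lt(max(abs(f_out - f_in)), 1e-10)
  # half-way ramp
  expect_equal(attractive_force(c(0.05, 0, 0), c(0, 0, 0), cfg),
               c(2 * 0.05 * 0.5, 0, 0))
})

test_that("static force is the stiffness-scaled contour error, normal to the curve", {
  seg <- nurbs_fit(line_trajectory(c(0, 0, 0), c(10, 0, 0), n = 20),
                   n_control = 4)
  cfg <- guidance_config(k_s = 5)

  expect_equal(static_force(seg, c(3, 0.2, 0), cfg), c(0, -1, 0),
               tolerance = 1e-6)
  on_curve <- as.numeric(evaluate_curve(seg, 0.6))
  expect_lt(max(abs(static_force(seg, on_curve, cfg))), 1e-6)

  set.seed(19)
  cv <- random_curve(seed = 601, degree = 3, m = 8)
  for (k in 1:10) {
    D <- rnorm(3, sd = 2)
    cp <- closest_point(cv, D)
    F <- static_force(cv, D, cfg)
    eps <- cp$point - D
    # parallel to the contour error with magnitude k_s * |eps|
    expect_equal(F, cfg$k_s * eps, tolerance = 1e-9)
    # normal to the tangent at interior minimizers
    if (cp$u > 1e-3 && cp$u < 1 - 1e-3 && cp$distance > 1e-6) {
      tang <- as.numeric(arthroguide:::curve_derivs(cv, cp$u)$C1)
      cosang <- sum(F * tang) / sqrt(sum(F^2) * sum(tang^2))
      expect_lt(abs(cosang), 1e-6)
    }
  }
})

test_that("time-dependent force pulls toward the scheduled target point", {
  # constant curve: target point is (1, 1, 1) at every time
  cv <- arthroguide:::new_nurbs_curve(3, c(0, 0, 0, 0, 1, 1, 1, 1),
                                      matrix(1, 4, 3), rep(1, 4), 0, 10)
  cfg <- guidance_config(k_d = 2, mode = "time_dependent")
  expect_equal(time_dependent_force(cv, 5, c(0, 0, 0), cfg), c(2, 2, 2))
  expect_equal(time_dependent_force(cv, 5, c(1, 1, 1), cfg), c(0, 0, 0))
  expect_warning(time_dependent_force(cv, 99, c(0, 0, 0), cfg), "clamped")

  # normal + tangential decomposition reconstructs the force exactly
  cv2 <- random_curve(seed = 602, degree = 3, m = 7)
  cfg2 <- guidance_config(k_d = 3, mode = "time_dependent")
  t_t <- map_time(cv2, 0.37)
  D <- c(1, -2, 0.5)
  F <- time_dependent_force(cv2, t_t, D, cfg2)
  tang <- as.numeric(arthroguide:::curve_derivs(cv2, 0.37)$C1)
  tang <- tang / sqrt(sum(tang^2))
  F_tan <- sum(F * tang) * tang
  expect_lt(max(abs((F_tan + (F - F_tan)) - F)), 1e-12)
})

test_that("training strength scales guidance linearly from full to none", {
  F <- c(2, 0, 0)
  expect_identical(apply_training_strength(F, 0), F)
  expect_identical(apply_training_strength(F, 1), c(0, 0, 0))
  expect_identical(apply_training_strength(F, 0.5), c(1, 0, 0))
  expect_error(apply_training_strength(F, 1.2), "invalid training strength")
  expect_error(guidance_config(v = -0.1), "invalid training strength")
})

test_that("the guidance state machine attracts, then tracks, and never reverts", {
  seg <- nurbs_fit(line_trajectory(c(0, 0, 0), c(10, 0, 0), n = 20),
                   n_control = 4)
  cfg <- guidance_config(k_A = 2, d_A = 0.5, d_t = 0.1, k_s = 5)
  st <- guidance_state()
  expect_identical(st$phase, "initialization")

  far <- guidance_step(st, seg, c(5, 5, 5), now = 0, cfg = cfg)
  expect_identical(far$state$phase, "initialization")
  expect_equal(far$force, attractive_force(c(0, 0, 0), c(5, 5, 5), cfg))

  near <- guidance_step(far$state, seg, c(0.05, 0, 0), now = 0.5, cfg = cfg)
  expect_identical(near$state$phase, "tracking")
  # once tracking, a far excursion stays in tracking (static pull back)
  again <- guidance_step(near$state, seg, c(5, 5, 5), now = 1, cfg = cfg)
  expect_identical(again$state$phase, "tracking")
  expect_equal(again$force, static_force(seg, c(5, 5, 5), cfg))
})

test_that("force at strength v equals (1 - v) times the full-guidance force in every regime", {
  seg <- nurbs_fit(line_trajectory(c(0, 0, 0), c(10, 0, 0), n = 20),
                   n_control = 4)
  set.seed(42)
  for (mode in c("static", "time_dependent")) {
    for (k in 1:10) {
      v <- runif(1)
      cfg0 <- guidance_config(v = 0, mode = mode)
      cfgv <- guidance_config(v = v, mode = mode)
      D <- rnorm(3, sd = 4)
      # initialization regime
      expect_equal(guidance_step(guidance_state(), seg, D + 20, 0, cfgv)$force,
                   (1 - v) * guidance_step(guidance_state(), seg, D + 20, 0, cfg0)$force,
                   tolerance = 1e-12)
      # tracking regime
      st <- guidance_step(guidance_state(), seg, c(0, 0, 0), 0, cfg0)$state
      expect_equal(guidance_step(st, seg, D, 1, cfgv)$force,
                   (1 - v) * guidance_step(st, seg, D, 1, cfg0)$force,
                   tolerance = 1e-12)
    }
  }
  # v = 1 removes guidance entirely
  st <- guidance_step(guidance_state(), seg, c(0, 0, 0), 0,
                      guidance_config(v = 1))$state
  out <- guidance_step(st, seg, c(7, 3, -2), 1, guidance_config(v = 1))
  expect_identical(out$force, c(0, 0, 0))
})
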