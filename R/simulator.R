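#' Parameters of the synthetic expert inspection path
#'
#' The synthetic-data engine stands in for the clinical recording: a smooth
#' path through random waypoints inside a knee-scale workspace box, sampled
#' at the optical tracker's frame rate. Defaults emulate a short inspection
#' pass: a 10 cm workspace, ~20 s duration, 30 Hz capture.
#'
#' @param workspace_extent length-3 box edge lengths (cm), centered at the
#'   origin.
#' @param n_waypoints number of interior waypoints (>= 4).
#' @param duration recording duration (s).
#' @param smoothness cardinal-spline tension in `[0, 1]`: 1 gives
#'   Catmull-Rom tangents, smaller values flatten the path between
#'   waypoints.
#' @param frame_rate tracker capture rate (Hz).
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return An object of class `expert_path_params`.
#' @export
expert_path_params <- function(workspace_extent = c(10, 10, 10),
                               n_waypoints = 8, duration = 20,
                               smoothness = 0.5, frame_rate = 30, seed = 1) {
  stopifnot(duration > 0, n_waypoints >= 4, frame_rate > 0,
            smoothness >= 0, smoothness <= 1, all(workspace_extent > 0))
  structure(list(workspace_extent = as.numeric(workspace_extent),
                 n_waypoints = as.integer(n_waypoints),
                 duration = duration, smoothness = smoothness,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "expert_path_params")
}

# Cubic Hermite (cardinal) spline through waypoints, per axis.
hermite_path <- function(times, pts, tension, tout) {
  k <- nrow(pts)
  tang <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    lo <- max(1, i - 1); hi <- min(k, i + 1)
    tang[i, ] <- tension * (pts[hi, ] - pts[lo, ]) / (times[hi] - times[lo])
  }
  seg <- pmin(findInterval(tout, times, rightmost.closed = TRUE), k - 1)
  h <- times[seg + 1] - times[seg]
  s <- (tout - times[seg]) / h
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * pts[seg, ] + (h10 * h) * tang[seg, ] +
    h01 * pts[seg + 1, ] + (h11 * h) * tang[seg + 1, ]
}

#' Generate a synthetic expert inspection trajectory
#'
#' Draws waypoints inside the inner 75% of the workspace box (margin against
#' spline overshoot), connects them with a cardinal cubic spline, samples at
#' the frame rate, and attaches a slowly rotating unit-quaternion
#' orientation. Deterministic given the seed.
#'
#' @param params an [expert_path_params()].
#' @return A `trajectory`.
#' @export
generate_expert_trajectory <- function(params) {
  stopifnot(inherits(params, "expert_path_params"))
  with_seed(params$seed, {
    k <- params$n_waypoints
    half <- params$workspace_extent / 2
    way <- cbind(stats::runif(k, -0.75 * half[1], 0.75 * half[1]),
                 stats::runif(k, -0.75 * half[2], 0.75 * half[2]),
                 stats::runif(k, -0.75 * half[3], 0.75 * half[3]))
    wt <- seq(0, params$duration, length.out = k)
    tt <- seq(0, params$duration, by = 1 / params$frame_rate)
    pos <- hermite_path(wt, way, params$smoothness, tt)
    axis <- stats::rnorm(3); axis <- axis / vnorm(axis)
    total <- stats::runif(1, 0, pi / 2)
    ang <- total * tt / params$duration
    quat <- cbind(cos(ang / 2), outer(sin(ang / 2), axis))
    trajectory(tt, pos, quat, source = "left")
  })
}

#' Optical tracker noise model
#'
#' @param sigma per-axis Gaussian position noise SD (cm).
#' @param dropout_prob per-frame probability that the marker is missed and
#'   the previous pose is held.
#' @param frame_rate capture rate (Hz).
#' @param seed RNG seed.
#' @return An object of class `tracker_noise_params`.
#' @export
tracker_noise_params <- function(sigma = 0.05, dropout_prob = 0.02,
                                 frame_rate = 30, seed = 1) {
  stopifnot(sigma >= 0, dropout_prob >= 0, dropout_prob < 1, frame_rate > 0)
  structure(list(sigma = sigma, dropout_prob = dropout_prob,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "tracker_noise_params")
}

#' Corrupt a trajectory with tracker noise and dropouts
#'
#' Adds i.i.d. Gaussian offsets per axis, then replaces each dropped frame
#' (probability `dropout_prob`, never the first frame) with the previous
#' emitted pose, marked `source = "held"`. Consecutive dropouts repeat the
#' same pose, mirroring the hold-last-pose rule of the tracking chain.
#'
#' @param traj a `trajectory`.
#' @param noise a [tracker_noise_params()].
#' @return A `trajectory` of the same length.
#' @export
add_tracking_noise <- function(traj, noise) {
  stopifnot(inherits(noise, "tracker_noise_params"))
  out <- as.data.frame(traj)
  n <- nrow(out)
  with_seed(noise$seed, {
    if (noise$sigma > 0) {
      out$x <- out$x + stats::rnorm(n, sd = noise$sigma)
      out$y <- out$y + stats::rnorm(n, sd = noise$sigma)
      out$z <- out$z + stats::rnorm(n, sd = noise$sigma)
    }
    if (noise$dropout_prob > 0 && n > 1) {
      drop <- c(FALSE, stats::runif(n - 1) < noise$dropout_prob)
      cols <- c("x", "y", "z", "qw", "qx", "qy", "qz")
      for (i in which(drop)) {
        out[i, cols] <- out[i - 1, cols]
        out$source[i] <- "held"
      }
    }
  })
  as_trajectory(out)
}

#' Simulated trainee operator
#'
#' A damped point mass holding the virtual stylus: the operator intends to
#' follow a target that advances along the reference curve, but the intended
#' point is corrupted by Gaussian "skill" noise. Larger `skill_sigma` means
#' a shakier novice; `speed_factor` rescales the recorded pacing. Defaults
#' are desk-scale values chosen to give stable 30 Hz integration and
#' unguided path errors of a few millimetres, the same order as recorded
#' novice performance.
#'
#' @param mass point mass (device-normalized).
#' @param damping viscous damping coefficient.
#' @param intent_gain proportional pull stiffness toward the intended point
#'   (force/cm).
#' @param skill_sigma SD of the Gaussian intent noise (cm).
#' @param speed_factor multiplier on the recorded pacing.
#' @param seed RNG seed.
#' @return An object of class `operator_model`.
#' @export
operator_model <- function(mass = 0.1, damping = 3, intent_gain = 20,
                           skill_sigma = 0.3, speed_factor = 1, seed = 1) {
  stopifnot(mass > 0, damping > 0, intent_gain > 0, skill_sigma >= 0,
            speed_factor > 0)
  structure(list(mass = mass, damping = damping, intent_gain = intent_gain,
                 skill_sigma = skill_sigma, speed_factor = speed_factor,
                 seed = as.integer(seed)), class = "operator_model")
}

#' Simulate one training session on a reference curve
#'
#' Integrates the operator's damped point mass with semi-implicit Euler at
#' the 30 Hz tracker rate. The probe starts offset from the curve start; the
#' guidance state machine first attracts it to `C(t0)`, then the target
#' advances along the curve at `speed_factor` times the recorded pacing
#' while the operator pulls toward the (noise-corrupted) target and the
#' guidance force acts per the configured mode and training strength. The
#' session ends when the target reaches the end of the recording. The
#' returned trajectory covers the tracking phase (the inspection itself).
#'
#' @param curve a `nurbs_curve` (the expert reference).
#' @param operator an [operator_model()].
#' @param cfg a [guidance_config()].
#' @param seed session RNG seed (overrides `operator$seed` when given).
#' @param start_offset initial distance of the probe from `C(t0)` (cm).
#' @return A list of class `training_session` with `trajectory`,
#'   `operation_time` (s, including initialization), `seed` and the echoed
#'   configuration.
#' @export
simulate_session <- function(curve, operator = operator_model(),
                             cfg = guidance_config(), seed = NULL,
                             start_offset = 1) {
  stopifnot(inherits(curve, "nurbs_curve"), inherits(operator, "operator_model"),
            inherits(cfg, "guidance_config"))
  seed <- as.integer(seed %||% operator$seed)
  dt <- 1 / 30
  span <- curve$t1 - curve$t0
  du <- operator$speed_factor / span * dt
  max_steps <- ceiling(10 * (1 / du + 300))
  with_seed(seed, {
    dir0 <- stats::rnorm(3); dir0 <- dir0 / vnorm(dir0)
    x <- as.numeric(evaluate_curve(curve, 0)) + start_offset * dir0
    vel <- c(0, 0, 0)
    state <- guidance_state()
    target_u <- 0
    t <- 0
    times <- numeric(0)
    rec <- list()
    step <- 0L
    V_prev <- c(0, 0, 0)
    # feedforward gain matched to the discrete update so that exact tracking
    # of the advancing target is a fixed point of the integrator
    ff_gain <- operator$mass * (1 - operator$damping * dt / operator$mass)
    repeat {
      step <- step + 1L
      if (step > max_steps) stop("simulation diverged: step limit reached")
      tracking <- state$phase == "tracking"
      if (tracking) target_u <- min(target_u + du, 1)
      x_t <- as.numeric(evaluate_curve(curve, target_u))
      v_t <- if (tracking) {
        (as.numeric(evaluate_curve(curve, min(target_u + du, 1))) - x_t) / dt
      } else c(0, 0, 0)
      a_t <- (v_t - V_prev) / dt
      V_prev <- v_t
      eps <- stats::rnorm(3, sd = operator$skill_sigma)
      F_op <- operator$intent_gain * (x_t + eps - x) +
        operator$damping * (v_t - vel) + ff_gain * a_t
      gs <- guidance_step(state, curve, x, now = t, cfg = cfg)
      state <- gs$state
      acc <- (F_op + gs$force) / operator$mass
      if (!all(is.finite(acc)))
        stop(sprintf("simulation diverged at step %d", step))
      vel <- vel + acc * dt
      x <- x + vel * dt
      t <- t + dt
      if (state$phase == "tracking") {
        rec[[length(rec) + 1L]] <- x
        times <- c(times, t)
      }
      if (tracking && target_u >= 1) break
    }
    traj <- trajectory(times, do.call(rbind, rec), source = "left")
    structure(list(trajectory = traj, operation_time = t, seed = seed,
                   operator = operator, guidance = cfg),
              class = "training_session")
  })
}

#' @export
print.training_session <- function(x, ...) {
  cat(sprintf(
    "Training session: %d tracked samples, operation time %.3f s (seed %d, v = %g, mode %s)\n",
    nrow(x$trajectory), x$operation_time, x$seed, x$guidance$v,
    x$guidance$mode))
  invisible(x)
}

#' Simulate trainee sessions from a fitted trajectory curve
#'
#' `simulate()` on a `nurbs_curve` runs `nsim` virtual-subject training
#' sessions against the fitted expert curve, one derived RNG stream per
#' subject so cohorts are reproducible subject-by-subject.
#'
#' @param object a `nurbs_curve`.
#' @param nsim number of virtual subjects.
#' @param seed master seed; subject `i` uses `seed * 100 + i`.
#' @param operator an [operator_model()].
#' @param cfg a [guidance_config()].
#' @param ... passed to [simulate_session()].
#' @return A list of `training_session` objects, length `nsim`.
#' @export
simulate.nurbs_curve <- function(object, nsim = 1, seed = 1,
                                 operator = operator_model(),
                                 cfg = guidance_config(), ...) {
  lapply(seq_len(nsim), function(i)
    simulate_session(object, operator, cfg,
                     seed = as.integer(seed) * 100L + i, ...))
}
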