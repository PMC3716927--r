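#' Force-guidance configuration
#'
#' Parameters of the three guiding force laws. Units are device-normalized
#' force per cm of displacement for the stiffnesses and cm for the radii;
#' no Newton calibration is implied. Numeric defaults are package choices
#' for a desk-scale knee workspace, not measured device values.
#'
#' @param k_A attractive stiffness (force/cm): gain of the initialization
#'   pull toward the start of the reference curve.
#' @param d_A outer attraction radius (cm): beyond it the attractive force
#'   saturates at magnitude `k_A * d_A`.
#' @param d_t inner dead-zone radius (cm): inside it the attractive force is
#'   zero and the session switches to tracking; `0 < d_t < d_A`.
#' @param k_s static (contour-error) stiffness (force/cm).
#' @param k_d time-dependent (tracking-error) stiffness (force/cm).
#' @param v training strength in `[0, 1]`: 0 = full guidance, 1 = guidance
#'   removed.
#' @param mode `"static"` (guide toward the closest curve point) or
#'   `"time_dependent"` (guide toward the time-scheduled target point).
#' @param smooth_dead_zone if `TRUE`, ramp the attractive force linearly to
#'   zero between `d_t` and the curve start instead of the literal jump to
#'   zero at `d_t`.
#' @param playback_rate speed at which the time-dependent target replays the
#'   recorded clock (1 = recorded pacing).
#' @return An object of class `guidance_config`.
#' @export
guidance_config <- function(k_A = 5, d_A = 1, d_t = 0.1, k_s = 5, k_d = 5,
                            v = 0, mode = c("static", "time_dependent"),
                            smooth_dead_zone = FALSE, playback_rate = 1) {
  mode <- match.arg(mode)
  if (!(d_t > 0 && d_t < d_A)) stop("require 0 < d_t < d_A")
  if (min(k_A, k_s, k_d) < 0) stop("stiffnesses must be non-negative")
  if (v < 0 || v > 1) stop("invalid training strength: v must be in [0, 1]")
  if (playback_rate <= 0) stop("playback_rate must be positive")
  structure(list(k_A = k_A, d_A = d_A, d_t = d_t, k_s = k_s, k_d = k_d,
                 v = v, mode = mode, smooth_dead_zone = smooth_dead_zone,
                 playback_rate = playback_rate), class = "guidance_config")
}

#' @export
print.guidance_config <- function(x, ...) {
  cat(sprintf(
    "Guidance config: mode %s, v = %g\n  k_A = %g, d_A = %g cm, d_t = %g cm, k_s = %g, k_d = %g\n",
    x$mode, x$v, x$k_A, x$d_A, x$d_t, x$k_s, x$k_d))
  invisible(x)
}

#' Attractive initialization force
#'
#' Pulls the probe toward the start of the reference curve. Outside the
#' attraction radius `d_A` the pull has constant magnitude `k_A * d_A`;
#' between `d_t` and `d_A` it decreases linearly (`k_A` times the offset);
#' inside the dead zone `d_t` it is zero.
#'
#' @param anchor the target point `C(t0)` (3-vector, cm).
#' @param D current probe position (3-vector, cm).
#' @param cfg a [guidance_config()].
#' @return Force 3-vector.
#' @export
attractive_force <- function(anchor, D, cfg) {
  diff <- as.numeric(anchor) - as.numeric(D)
  r <- vnorm(diff)
  if (r == 0) return(c(0, 0, 0))
  if (r > cfg$d_A) {
    cfg$k_A * cfg$d_A * diff / r
  } else if (r >= cfg$d_t) {
    cfg$k_A * diff
  } else if (cfg$smooth_dead_zone) {
    cfg$k_A * diff * (r / cfg$d_t)
  } else {
    c(0, 0, 0)
  }
}

#' Static (contour-error) guiding force
#'
#' Projects the probe onto the reference curve and pulls along the contour
#' error `eps = C(u*) - D` with stiffness `k_s`. At interior minimizers the
#' force is normal to the curve tangent, guiding the probe back to the path
#' without imposing pacing.
#'
#' @param curve a `nurbs_curve`.
#' @param D probe position (3-vector, cm).
#' @param cfg a [guidance_config()].
#' @return Force 3-vector.
#' @export
static_force <- function(curve, D, cfg) {
  cp <- closest_point(curve, D)
  cfg$k_s * (cp$point - as.numeric(D))
}

#' Time-dependent (tracking-error) guiding force
#'
#' Pulls the probe toward the time-scheduled target point `C(u(t_t))` on the
#' reference curve with stiffness `k_d`, reproducing the expert's pacing as
#' well as geometry. The tracking error combines normal and tangential
#' components.
#'
#' @param curve a `nurbs_curve`.
#' @param t_t target time (s); values outside the curve's window are clamped
#'   with a warning.
#' @param D probe position (3-vector, cm).
#' @param cfg a [guidance_config()].
#' @return Force 3-vector.
#' @export
time_dependent_force <- function(curve, t_t, D, cfg) {
  if (t_t < curve$t0 || t_t > curve$t1) {
    warning("target time outside the curve window; clamped")
    t_t <- clamp(t_t, curve$t0, curve$t1)
  }
  target <- as.numeric(evaluate_curve(curve, time_to_param(curve, t_t)))
  cfg$k_d * (target - as.numeric(D))
}

#' Scale a guiding force by the training strength
#'
#' Returns `(1 - v) * F`: full guidance at `v = 0`, none at `v = 1`.
#'
#' @param F force 3-vector.
#' @param v training strength in `[0, 1]`.
#' @return Scaled force 3-vector.
#' @export
apply_training_strength <- function(F, v) {
  if (v < 0 || v > 1) stop("invalid training strength: v must be in [0, 1]")
  (1 - v) * F
}

#' Initial guidance session state
#'
#' A session starts in the `initialization` phase (attractive pull toward
#' the curve start) and switches permanently to `tracking` once the probe
#' enters the dead zone around `C(t0)`.
#'
#' @return An object of class `guidance_state`.
#' @export
guidance_state <- function() {
  structure(list(phase = "initialization", started_at = NA_real_),
            class = "guidance_state")
}

#' One step of the guidance state machine
#'
#' Dispatches to the attractive force during initialization, then to the
#' static or time-dependent force once tracking has begun, and finally
#' scales the result by the training strength.
#'
#' @param state a [guidance_state()].
#' @param curve a `nurbs_curve`.
#' @param D probe position (3-vector, cm).
#' @param now current session time (s), used to advance the time-dependent
#'   target.
#' @param cfg a [guidance_config()].
#' @return A list with `force` (3-vector) and the updated `state`.
#' @export
guidance_step <- function(state, curve, D, now, cfg) {
  anchor <- as.numeric(evaluate_curve(curve, 0))
  if (state$phase == "initialization") {
    if (vnorm(anchor - as.numeric(D)) <= cfg$d_t) {
      state$phase <- "tracking"
      state$started_at <- now
    } else {
      F <- attractive_force(anchor, D, cfg)
      return(list(force = apply_training_strength(F, cfg$v), state = state))
    }
  }
  F <- if (cfg$mode == "static") {
    static_force(curve, D, cfg)
  } else {
    t_t <- clamp(curve$t0 + (now - state$started_at) * cfg$playback_rate,
                 curve$t0, curve$t1)
    time_dependent_force(curve, t_t, D, cfg)
  }
  list(force = apply_training_strength(F, cfg$v), state = state)
}
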