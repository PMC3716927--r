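#' @export
print.nurbs_curve <- function(x, ...) {
  m <- nrow(x$control_points)
  cat(sprintf("NURBS trajectory curve: degree %d, %d control points\n",
              x$degree, m))
  cat(sprintf("  time window: [%.3f, %.3f] s\n", x$t0, x$t1))
  if (!is.null(x$data)) {
    n <- nrow(x$data)
    rms <- sqrt(mean(rowSums(x$residuals^2)))
    cat(sprintf("  fitted to %d samples (compression %d:%d), RMS residual %.4g cm\n",
                n, n, m, rms))
  }
  invisible(x)
}

#' @export
summary.nurbs_curve <- function(object, ...) {
  res <- if (!is.null(object$residuals))
    sqrt(rowSums(object$residuals^2)) else NULL
  out <- list(degree = object$degree,
              n_control = nrow(object$control_points),
              n_data = if (!is.null(object$data)) nrow(object$data) else NA,
              knots = object$knots,
              time_window = c(object$t0, object$t1),
              rms_residual = if (!is.null(res)) sqrt(mean(res^2)) else NA,
              max_residual = if (!is.null(res)) max(res) else NA,
              weights_unit = all(object$weights == 1))
  class(out) <- "summary.nurbs_curve"
  out
}

#' @export
print.summary.nurbs_curve <- function(x, ...) {
  cat(sprintf("NURBS trajectory curve (degree %d)\n", x$degree))
  cat(sprintf("  control points: %d  (data samples: %s)\n", x$n_control,
              format(x$n_data)))
  cat(sprintf("  knots: %d (%d interior)\n", length(x$knots),
              length(x$knots) - 2 * (x$degree + 1)))
  cat(sprintf("  time window: [%.3f, %.3f] s\n",
              x$time_window[1], x$time_window[2]))
  if (!is.na(x$rms_residual))
    cat(sprintf("  residuals: RMS %.4g cm, max %.4g cm\n",
                x$rms_residual, x$max_residual))
  cat(if (x$weights_unit) "  unit weights (polynomial B-spline)\n"
      else "  non-unit rational weights\n")
  invisible(x)
}

#' @export
coef.nurbs_curve <- function(object, ...) {
  cp <- object$control_points
  colnames(cp) <- c("x", "y", "z")
  cp
}

#' Predict positions along a fitted trajectory curve
#'
#' @param object a `nurbs_curve`.
#' @param u curve parameters in `[0, 1]`; alternatively pass `t` (seconds
#'   within the recorded window) which is converted through [time_to_param()].
#' @param t optional times (s); overrides `u`.
#' @param ... unused.
#' @return Matrix of positions (cm) with columns x, y, z.
#' @export
predict.nurbs_curve <- function(object, u = seq(0, 1, length.out = 101),
                                t = NULL, ...) {
  if (!is.null(t)) u <- time_to_param(object, t)
  out <- evaluate_curve(object, u)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
fitted.nurbs_curve <- function(object, ...) object$fitted.values

#' @export
residuals.nurbs_curve <- function(object, ...) object$residuals

#' Plot a fitted trajectory curve over its data
#'
#' Two planar projections (x-y and x-z) of the raw tracked samples and the
#' smoothed curve.
#'
#' @param x a `nurbs_curve`.
#' @param n number of curve evaluation points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nurbs_curve <- function(x, n = 200, ...) {
  cv <- predict(x, u = seq(0, 1, length.out = n))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (ax in c("y", "z")) {
    if (!is.null(x$data)) {
      graphics::plot(x$data$x, x$data[[ax]], pch = 16, cex = 0.4,
                     col = "grey60", xlab = "x (cm)",
                     ylab = paste0(ax, " (cm)"), ...)
      graphics::lines(cv[, "x"], cv[, ax], col = "firebrick", lwd = 2)
    } else {
      graphics::plot(cv[, "x"], cv[, ax], type = "l", col = "firebrick",
                     lwd = 2, xlab = "x (cm)", ylab = paste0(ax, " (cm)"), ...)
    }
  }
  invisible(x)
}
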