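#' Timestamped 6-DOF trajectory samples
#'
#' A trajectory is a data frame with one row per tracked sample: `time`
#' (seconds since tracking start, strictly increasing), `x`, `y`, `z`
#' (cm, marker pose expressed in the left-camera convention), a unit
#' quaternion `qw`, `qx`, `qy`, `qz` (w-first, right-handed), and `source`
#' marking the provenance of each pose: `"left"` or `"right"` for the camera
#' that saw the marker, `"held"` for a dropout frame repeating the previous
#' pose.
#'
#' @param time numeric vector of sample times (s), strictly increasing.
#' @param position n x 3 matrix of positions (cm).
#' @param orientation n x 4 matrix of unit quaternions (w, x, y, z), or
#'   `NULL` for identity.
#' @param source character vector (recycled) in `"left"`, `"right"`, `"held"`.
#' @return A data frame of class `trajectory`.
#' @export
trajectory <- function(time, position, orientation = NULL,
                       source = "left") {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- length(time)
  stopifnot(nrow(position) == n)
  if (is.null(orientation))
    orientation <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
  orientation <- matrix(as.numeric(orientation), ncol = 4)
  df <- data.frame(time = as.numeric(time),
                   x = position[, 1], y = position[, 2], z = position[, 3],
                   qw = orientation[, 1], qx = orientation[, 2],
                   qy = orientation[, 3], qz = orientation[, 4],
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  as_trajectory(df)
}

#' Validate a data frame as a trajectory
#' @param df data frame with the trajectory columns.
#' @return The validated `trajectory`.
#' @export
as_trajectory <- function(df) {
  needed <- c("time", "x", "y", "z", "qw", "qx", "qy", "qz", "source")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trajectory is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[needed]
  if (nrow(df) >= 2 && any(diff(df$time) <= 0))
    stop("trajectory timestamps must be strictly increasing")
  qn <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
  if (any(abs(qn - 1) > 1e-6)) {
    warning("non-unit quaternion(s) renormalized")
  }
  off <- abs(qn - 1) > 1e-12
  if (any(off)) {
    qcols <- c("qw", "qx", "qy", "qz")
    df[off, qcols] <- df[off, qcols] / qn[off]
  }
  bad <- setdiff(unique(df$source), c("left", "right", "held"))
  if (length(bad))
    stop("unknown trajectory source value(s): ", paste(bad, collapse = ", "))
  class(df) <- c("trajectory", "data.frame")
  df
}

traj_positions <- function(traj) {
  unname(as.matrix(traj[c("x", "y", "z")]))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over %.3f s (%s)\n",
              nrow(x), diff(range(x$time)),
              paste(sprintf("%s: %d", names(table(x$source)),
                            as.integer(table(x$source))), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
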