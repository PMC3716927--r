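#' Write a trajectory to CSV
#'
#' Schema: `time,x,y,z,qw,qx,qy,qz,source`; time and coordinates printed
#' with 6 decimals.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- c("time", "x", "y", "z", "qw", "qx", "qy", "qz")
  for (col in num) df[[col]] <- sprintf("%.6f", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Validates the header, monotone timestamps and quaternion norms
#' (renormalizing with a warning beyond 1e-6); malformed rows are rejected
#' with their line number.
#'
#' @param path CSV file written by [write_trajectory_csv()].
#' @return A `trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time", "x", "y", "z", "qw", "qx", "qy", "qz", "source")
  if (!identical(names(df), needed))
    stop("unexpected trajectory header: expected ", paste(needed, collapse = ","))
  num <- needed[1:8]
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d", col, bad[1] + 1L))
    df[[col]] <- v
  }
  as_trajectory(df)
}

#' Write a fitted curve to JSON
#'
#' Serializes degree, knots, control points, weights and the time window at
#' full double precision, so write/read round-trips are exact.
#'
#' @param curve a `nurbs_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_json <- function(curve, path) {
  obj <- list(degree = curve$degree,
              knots = curve$knots,
              control_points = unname(curve$control_points),
              weights = curve$weights,
              t0 = curve$t0, t1 = curve$t1)
  # 17 significant digits: doubles survive the round-trip bit-exactly
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a curve JSON
#' @param path file written by [write_curve_json()].
#' @return A `nurbs_curve` (without fitting data).
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_nurbs_curve(obj$degree, obj$knots,
                  matrix(as.numeric(obj$control_points), ncol = 3),
                  obj$weights, as.numeric(obj$t0), as.numeric(obj$t1))
}

#' Read a stereo rig configuration (YAML or JSON)
#'
#' Expected fields: `left` and `right` camera blocks (`K`: 9 numbers
#' row-major, `width`, `height`), `marker_side_cm`, and `T_rl` with
#' `quaternion` (w, x, y, z) and `translation`.
#'
#' @param path config file.
#' @return A [stereo_rig()].
#' @export
read_rig_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cam <- function(b) {
    K <- matrix(as.numeric(b$K), 3, 3, byrow = TRUE)
    camera_intrinsics(K[1, 1], K[2, 2], K[1, 3], K[2, 3], b$width, b$height)
  }
  T_rl <- rigid_transform(matrix_from_quat(as.numeric(cfg$T_rl$quaternion)),
                          as.numeric(cfg$T_rl$translation))
  stereo_rig(cam(cfg$left), cam(cfg$right), T_rl, cfg$marker_side_cm)
}

#' Write a stereo rig configuration to YAML
#' @param rig a [stereo_rig()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rig_config <- function(rig, path) {
  cam <- function(K) list(K = as.numeric(t(K$matrix)),
                          width = K$width, height = K$height)
  yaml::write_yaml(list(
    left = cam(rig$K_l), right = cam(rig$K_r),
    marker_side_cm = rig$side_length,
    T_rl = list(quaternion = as.numeric(quat_from_matrix(rig$T_rl$rotation)),
                translation = as.numeric(rig$T_rl$translation))), path,
    precision = 15)
  invisible(path)
}

#' Read a cohort summary CSV
#'
#' Schema: `subject,condition,session,avg_cm,sd_cm,time_s`. The packaged
#' fixtures (`system.file("extdata", ..., package = "arthroguide")`)
#' transcribe the published eight-subject study tables in this format.
#'
#' @param path CSV file.
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("unreadable cohort CSV: ", conditionMessage(e)))
  if (nrow(df) == 0 || !all(c("subject", "condition", "session") %in% names(df)))
    stop("cohort CSV must have columns subject,condition,session,avg_cm,sd_cm,time_s")
  as_cohort_table(df)
}

#' Path to a packaged fixture
#' @param name file name under the package's `extdata/`.
#' @return Absolute path.
#' @export
arthroguide_fixture <- function(name) {
  p <- system.file("extdata", name, package = "arthroguide")
  if (p == "") stop("no packaged fixture named ", name)
  p
}
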