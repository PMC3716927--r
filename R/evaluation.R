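#' Normal path error of a trainee trajectory
#'
#' The skill metric: for every trainee sample, the shortest distance to the
#' expert's reference curve (orthogonal projection via the closest-point
#' search).
#'
#' @param trainee a `trajectory` (or data frame with x, y, z).
#' @param expert a `nurbs_curve`.
#' @return Numeric vector of distances (cm), one per trainee sample.
#' @export
normal_path_error <- function(trainee, expert) {
  X <- as.matrix(as.data.frame(trainee)[c("x", "y", "z")])
  closest_point_batch(expert, X)$distance
}

#' Per-session summary metrics
#'
#' @param errors non-empty vector of normal path errors (cm).
#' @param start_time,end_time session start / end (s).
#' @return An object of class `session_metrics` with `errors`, `avg`
#'   (mean, cm), `sd` (sample SD, n - 1), and `time` (s).
#' @export
session_metrics <- function(errors, start_time = 0, end_time = NA) {
  errors <- as.numeric(errors)
  if (length(errors) == 0) stop("empty session")
  if (any(errors < 0)) stop("errors must be non-negative")
  structure(list(errors = errors,
                 avg = mean(errors),
                 sd = if (length(errors) > 1) stats::sd(errors) else 0,
                 time = end_time - start_time),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("Session metrics: AVG %.3f cm, SD %.3f cm, time %.3f s (%d samples)\n",
              x$avg, x$sd, x$time, length(x$errors)))
  invisible(x)
}

#' Score a training session against the expert curve
#'
#' Convenience wrapper combining [normal_path_error()] and
#' [session_metrics()].
#'
#' @param session a `training_session` from [simulate_session()].
#' @param expert a `nurbs_curve`.
#' @return A `session_metrics` object.
#' @export
score_session <- function(session, expert) {
  err <- normal_path_error(session$trajectory, expert)
  session_metrics(err, 0, session$operation_time)
}

#' Validate a cohort summary table
#'
#' A cohort table holds per-subject session summaries in long format:
#' columns `subject`, `condition` (`"without"` / `"with"` guidance),
#' `session` (`"first"` / `"second"`), `avg_cm`, `sd_cm`, `time_s`.
#'
#' @param df data frame with the columns above.
#' @return A data frame of class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  needed <- c("subject", "condition", "session", "avg_cm", "sd_cm", "time_s")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[needed]
  bad <- setdiff(unique(df$session), c("first", "second"))
  if (length(bad)) stop("unknown session label(s): ", paste(bad, collapse = ", "))
  for (col in c("avg_cm", "sd_cm", "time_s")) {
    if (any(is.na(df[[col]])))
      stop(sprintf("missing value in column '%s' (subject %s)",
                   col, df$subject[which(is.na(df[[col]]))[1]]))
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

cohort_rows <- function(tbl, session) {
  out <- tbl[tbl$session == session, , drop = FALSE]
  out[order(out$subject), , drop = FALSE]
}

#' Mean relative reduction between two cohort conditions
#'
#' The headline comparison: the mean over subjects of the per-subject
#' relative reduction `1 - with/without`, computed on the second-session
#' rows (performance after five practice repetitions), expressed in
#' percent. Positive values mean the guided condition was better (lower).
#'
#' @param without,with_ `cohort_table`s for the unguided and guided
#'   conditions, same subject set.
#' @param field `"avg"` (mean normal path error) or `"time"` (operation
#'   time).
#' @param session which session rows to compare (default `"second"`).
#' @return Percent reduction (scalar).
#' @export
mean_relative_reduction <- function(without, with_,
                                    field = c("avg", "time"),
                                    session = "second") {
  field <- match.arg(field)
  col <- if (field == "avg") "avg_cm" else "time_s"
  a <- cohort_rows(without, session)
  b <- cohort_rows(with_, session)
  if (!identical(a$subject, b$subject))
    stop("cohort misalignment: subject sets differ")
  if (any(a[[col]] <= 0))
    stop("baseline values must be strictly positive")
  100 * mean(1 - b[[col]] / a[[col]])
}

#' Practice effect within one condition
#'
#' Per-subject change from the first to the second session of the same
#' condition, with counts of improved subjects (negative change).
#'
#' @param tbl a `cohort_table` containing both `first` and `second` session
#'   rows.
#' @return A data frame with per-subject `d_avg_cm`, `d_time_s` and logical
#'   `improved_avg`, `improved_time`; attributes `n_improved_avg`,
#'   `n_improved_time`.
#' @export
practice_effect <- function(tbl) {
  a <- cohort_rows(tbl, "first")
  b <- cohort_rows(tbl, "second")
  if (!identical(a$subject, b$subject))
    stop("cohort misalignment: subject sets differ")
  out <- data.frame(subject = a$subject,
                    d_avg_cm = b$avg_cm - a$avg_cm,
                    d_time_s = b$time_s - a$time_s)
  out$improved_avg <- out$d_avg_cm < 0
  out$improved_time <- out$d_time_s < 0
  attr(out, "n_improved_avg") <- sum(out$improved_avg)
  attr(out, "n_improved_time") <- sum(out$improved_time)
  out
}

#' Compare guided and unguided cohorts
#'
#' Bundles the two headline statistics (percent reduction in second-session
#' mean normal path error and in operation time) with the per-subject
#' details.
#'
#' @param without,with_ `cohort_table`s (same subjects).
#' @return An object of class `cohort_comparison`.
#' @export
cohort_comparison <- function(without, with_) {
  a <- cohort_rows(without, "second")
  b <- cohort_rows(with_, "second")
  if (!identical(a$subject, b$subject))
    stop("cohort misalignment: subject sets differ")
  per <- data.frame(subject = a$subject,
                    avg_without_cm = a$avg_cm, avg_with_cm = b$avg_cm,
                    time_without_s = a$time_s, time_with_s = b$time_s,
                    avg_reduction_pct = 100 * (1 - b$avg_cm / a$avg_cm),
                    time_reduction_pct = 100 * (1 - b$time_s / a$time_s))
  structure(list(
    error_reduction_pct = mean_relative_reduction(without, with_, "avg"),
    time_reduction_pct = mean_relative_reduction(without, with_, "time"),
    n_subjects = nrow(per),
    n_better_avg = sum(b$avg_cm < a$avg_cm),
    per_subject = per), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison over %d subjects (second session)\n",
              x$n_subjects))
  cat(sprintf("  mean normal path error: %.2f%% lower with guidance\n",
              x$error_reduction_pct))
  cat(sprintf("  operation time:         %.2f%% lower with guidance\n",
              x$time_reduction_pct))
  cat(sprintf("  subjects with lower error under guidance: %d of %d\n",
              x$n_better_avg, x$n_subjects))
  invisible(x)
}
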