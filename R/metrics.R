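#' Fraction of trajectories that reached the target region
#' @param trajs Non-empty list of `dni_trajectory` objects.
#' @return Fraction in `[0, 1]`.
#' @export
convergence_rate <- function(trajs) {
  if (length(trajs) == 0) stop("empty trajectory list", call. = FALSE)
  mean(vapply(trajs, function(tr) isTRUE(attr(tr, "converged")), logical(1)))
}

#' Steps to convergence of one trajectory
#' @param traj A `dni_trajectory`.
#' @return Step index of the first converged state, or `NA` if it never
#'   converged.
#' @export
steps_to_convergence <- function(traj) {
  attr(traj, "steps_to_convergence")
}

#' Mean integrated distance to target (MIDT)
#'
#' Mean over recorded states of the Euclidean distance from the target.
#'
#' @param traj A `dni_trajectory` (or data frame with `x_m`, `y_m`).
#' @param target Target position 2-vector; defaults to the trajectory's
#'   recorded target.
#' @return Distance (m).
#' @export
midt <- function(traj, target = attr(traj, "target")) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  if (is.null(target)) stop("no target supplied or recorded", call. = FALSE)
  mean(sqrt((traj$x_m - target[1])^2 + (traj$y_m - target[2])^2))
}

#' Root mean square error from the ideal trajectory
#'
#' Simulates the ideal trajectory from the same initial state under the
#' continuous desired field `F = -K (x - x0)` with the same plant, sampled on
#' the same step grid, and returns the root of the mean squared positional
#' deviation between actual and ideal.
#'
#' @param traj A `dni_trajectory`.
#' @param params The [plant_params()] used for the run.
#' @param field The [desired_field()].
#' @return RMSE (m).
#' @export
rmse_vs_ideal <- function(traj, params, field) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  start <- point_mass_state(c(traj$x_m[1], traj$y_m[1]),
                            c(traj$vx[1], traj$vy[1]), traj$time_s[1])
  if (nrow(traj) == 1) return(0)
  ideal <- ideal_trajectory(start, field, params, traj$time_s[-1])
  dx <- traj$x_m[-1] - ideal$x_m
  dy <- traj$y_m[-1] - ideal$y_m
  sqrt(mean(c(0, dx^2 + dy^2)))   # deviation at the shared start is zero
}

#' Summarize a set of trajectories
#'
#' @param trajs List of `dni_trajectory` objects.
#' @param params The [plant_params()] used for the runs.
#' @param field The [desired_field()].
#' @return Object of class `metric_report`: list with `per_trajectory` (data
#'   frame of converged flag, steps, RMSE, MIDT) and `summary`
#'   (convergence rate, mean steps among converged, mean RMSE, mean MIDT).
#' @export
metric_report <- function(trajs, params, field) {
  if (length(trajs) == 0) stop("empty trajectory list", call. = FALSE)
  per <- data.frame(
    trajectory = seq_along(trajs),
    converged = vapply(trajs, function(t) isTRUE(attr(t, "converged")),
                       logical(1)),
    steps = vapply(trajs, function(t) {
      s <- steps_to_convergence(t); if (is.na(s)) NA_real_ else as.numeric(s)
    }, numeric(1)),
    rmse_m = vapply(trajs, rmse_vs_ideal, numeric(1),
                    params = params, field = field),
    midt_m = vapply(trajs, function(t) midt(t), numeric(1)))
  summ <- list(
    n = nrow(per),
    convergence_rate = mean(per$converged),
    mean_steps = if (any(per$converged))
      mean(per$steps[per$converged]) else NA_real_,
    mean_rmse_m = mean(per$rmse_m),
    mean_midt_m = mean(per$midt_m))
  structure(list(per_trajectory = per, summary = summ),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("metric_report over %d trajectories\n", s$n))
  cat(sprintf("  convergence rate : %.3f\n", s$convergence_rate))
  cat(sprintf("  mean steps       : %s\n",
              if (is.na(s$mean_steps)) "-" else sprintf("%.2f", s$mean_steps)))
  cat(sprintf("  mean RMSE        : %.4f m\n", s$mean_rmse_m))
  cat(sprintf("  mean MIDT        : %.4f m\n", s$mean_midt_m))
  invisible(x)
}

#' Write a metric report to disk
#'
#' Per-trajectory values as CSV plus the summary as JSON next to it.
#'
#' @param report A [metric_report()].
#' @param path CSV path; the summary goes to `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report$per_trajectory, path, row.names = FALSE)
  jsonlite::write_json(report$summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
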