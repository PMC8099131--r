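#' Run the gait analysis on a trajectory set
#'
#' Common back half of the workflow: event detection, per-step
#' spatiotemporal parameters, participant summary, per-frame joint angles
#' and stride-normalized angle cycles.
#'
#' @param ts A `trajectory_set` (from [preprocess_pose()] or
#'   [marker_trajectories()]).
#' @param config Configuration from [default_config()].
#' @param label Free-text system label stored on the result.
#' @return Object of class `gait_analysis`: list with `trajectories`,
#'   `events`, `steps`, `summary`, `angles`, `cycles`, `label`.
#' @export
analyze_trajectories <- function(ts, config = default_config(),
                                 label = ts$provenance) {
  events <- detect_gait_events(ts,
                               min_period_s = config$min_period_s,
                               prominence_frac = config$prominence_frac,
                               boundary_s = config$boundary_s)
  steps <- compute_step_table(events, ts)
  angles <- joint_angle_series(ts)
  cycles <- normalize_strides(angles, events, ts,
                              n_samples = config$n_cycle_samples)
  structure(list(trajectories = ts, events = events, steps = steps,
                 summary = participant_summary(steps),
                 angles = angles, cycles = cycles, label = label),
            class = "gait_analysis")
}

#' Full analysis of a pose sequence
#'
#' Preprocesses raw pixel keypoints ([preprocess_pose()]) and runs
#' [analyze_trajectories()].
#'
#' @param pose A [pose_sequence()].
#' @param scaling A [compute_scaling()] calibration (or `s` in m/px).
#' @param config Configuration from [default_config()].
#' @return A `gait_analysis` object.
#' @export
analyze_pose <- function(pose, scaling, config = default_config()) {
  ts <- preprocess_pose(pose, scaling, config)
  analyze_trajectories(ts, config, label = ts$provenance)
}

#' Full analysis of a marker table
#'
#' Marker data from an optical reference system are assumed already
#' smooth and metric; only the trajectory assembly and the analysis back
#' half are applied.
#'
#' @param markers A `marker_table` from [read_marker_csv()].
#' @param config Configuration from [default_config()].
#' @return A `gait_analysis` object.
#' @export
analyze_markers <- function(markers, config = default_config()) {
  ts <- marker_trajectories(markers)
  analyze_trajectories(ts, config, label = "mocap")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> %s: %d events, %d steps\n", x$label,
              nrow(x$events), nrow(x$steps)))
  s <- x$summary
  cat(sprintf("  step time %.3f s, step length %.3f m, gait speed %.3f m/s\n",
              s$step_time$mean, s$step_length$mean, s$gait_speed))
  invisible(x)
}
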