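#' Required marker names for the marker-table interchange format
#'
#' The loader demands, at minimum, the landmarks the analysis consumes:
#' left/right ankle, knee, hip, toe and heel, the four pelvis markers
#' (left/right ASIS and PSIS, whose midpoint is the pelvis reference), and
#' a trunk reference (C7 equivalent).
#'
#' @return Character vector of marker base names.
#' @export
required_markers <- function() {
  c("ankle_l", "ankle_r", "knee_l", "knee_r", "hip_l", "hip_r",
    "toe_l", "toe_r", "heel_l", "heel_r",
    "asis_l", "asis_r", "psis_l", "psis_r", "c7")
}

#' Read a marker trajectory CSV
#'
#' Interchange format standing in for motion-capture exports: a header row
#' with a `time` column (seconds, uniformly sampled) and one `<marker>_x` /
#' `<marker>_y` column pair per marker, in meters, with x along the
#' direction of travel and y vertical (up positive).
#'
#' @param path CSV file path.
#' @param required Marker base names that must be present
#'   (default [required_markers()]).
#' @return A data frame of class `marker_table` with attribute
#'   `sampling_rate` (Hz).
#' @export
read_marker_csv <- function(path, required = required_markers()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("marker CSV lacks a 'time' column")
  need <- c(t(outer(required, c("_x", "_y"), paste0)))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("marker CSV missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(df)) stop("marker CSV contains missing values")
  dt <- diff(df$time)
  if (length(dt) == 0L || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("marker CSV time column is not uniformly sampled")
  structure(df, class = c("marker_table", "data.frame"),
            sampling_rate = 1 / dt[1])
}

#' Write a marker table to CSV
#' @param markers A `marker_table` (or compatible data frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_marker_csv <- function(markers, path) {
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}

#' Write / read gait events
#'
#' Events CSV with columns `side`, `event`, `time_s`, `frame_index`,
#' `boundary` — the interchange format for [detect_gait_events()] output.
#'
#' @param events A `gait_events` data frame.
#' @param path CSV path.
#' @return `write_events` invisibly returns `path`; `read_events` returns
#'   the `gait_events` data frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side", "event", "time_s", "frame_index", "boundary")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events CSV missing columns: ",
                         paste(miss, collapse = ", "))
  class(df) <- c("gait_events", "data.frame")
  df
}

#' Write / read a step table
#'
#' Per-step spatiotemporal records (one row per step) as CSV.
#'
#' @param steps A `step_table` data frame from [compute_step_table()].
#' @param path CSV path.
#' @return `write_step_table` invisibly returns `path`; `read_step_table`
#'   returns the `step_table` data frame.
#' @export
write_step_table <- function(steps, path) {
  utils::write.csv(as.data.frame(steps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_step_table
#' @export
read_step_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("step_table", "data.frame")
  df
}

#' Write / read joint-angle cycles (long format)
#'
#' Long CSV with columns `leg`, `joint`, `stride`, `cycle_pct`,
#' `angle_deg`; stride-cycle profiles from [normalize_strides()].
#'
#' @param cycles An `angle_cycles` object.
#' @param path CSV path.
#' @return `write_angle_cycles` invisibly returns `path`;
#'   `read_angle_cycles` returns an `angle_cycles` object.
#' @export
write_angle_cycles <- function(cycles, path) {
  rows <- list()
  pct <- attr(cycles, "cycle_pct")
  for (leg in names(cycles)) {
    for (joint in c("hip", "knee", "ankle")) {
      m <- cycles[[leg]][[joint]]
      if (is.null(m) || nrow(m) == 0L) next
      for (s in seq_len(nrow(m)))
        rows[[length(rows) + 1L]] <- data.frame(
          leg = leg, joint = joint, stride = s, cycle_pct = pct,
          angle_deg = m[s, ])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(leg = character(), joint = character(),
                        stride = integer(), cycle_pct = numeric(),
                        angle_deg = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_cycles
#' @export
read_angle_cycles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pct <- sort(unique(df$cycle_pct))
  out <- list()
  for (leg in unique(df$leg)) {
    out[[leg]] <- list()
    for (joint in c("hip", "knee", "ankle")) {
      d <- df[df$leg == leg & df$joint == joint, ]
      if (nrow(d) == 0L) next
      strides <- sort(unique(d$stride))
      m <- matrix(NA_real_, length(strides), length(pct))
      for (i in seq_along(strides))
        m[i, ] <- d$angle_deg[d$stride == strides[i]][order(d$cycle_pct[d$stride == strides[i]])]
      out[[leg]][[joint]] <- m
    }
    out[[leg]]$mean <- lapply(out[[leg]][c("hip", "knee", "ankle")],
                              function(m) if (!is.null(m)) colMeans(m))
    out[[leg]]$sd <- lapply(out[[leg]][c("hip", "knee", "ankle")],
                            function(m) if (!is.null(m)) apply(m, 2, stats::sd))
  }
  structure(out, class = "angle_cycles", cycle_pct = pct)
}

#' Write a comparison report as JSON
#'
#' @param report A `comparison_report` (nested list) from [compare_runs()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
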