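#' Convert a pose sequence to per-keypoint pixel trajectories
#'
#' Unpacks the frame array into `n x 25` coordinate matrices and applies
#' the missing-data convention: keypoints whose confidence is at or below
#' `confidence_threshold` become `NA` coordinates.
#'
#' @param pose A [pose_sequence()].
#' @param confidence_threshold Confidence at or below which a keypoint is
#'   treated as missing. The default 0 treats only undetected keypoints as
#'   missing.
#' @return An object of class `pixel_trajectories`: list with `x`, `y`,
#'   `conf` (`n x 25` matrices, columns named by keypoint), `frame_rate`,
#'   `camera_side`, `image_size` and logical `walking_frame`.
#' @export
as_pixel_trajectories <- function(pose, confidence_threshold = 0) {
  stopifnot(inherits(pose, "pose_sequence"))
  x <- pose$xyc[, , "x", drop = TRUE]
  y <- pose$xyc[, , "y", drop = TRUE]
  conf <- pose$xyc[, , "c", drop = TRUE]
  if (is.null(dim(x))) {  # single frame
    x <- matrix(x, 1L); y <- matrix(y, 1L); conf <- matrix(conf, 1L)
  }
  colnames(x) <- colnames(y) <- colnames(conf) <- body25_keypoints()
  miss <- conf <= confidence_threshold
  x[miss] <- NA_real_
  y[miss] <- NA_real_
  structure(list(x = x, y = y, conf = conf,
                 frame_rate = pose$frame_rate,
                 camera_side = pose$camera_side,
                 image_size = pose$image_size,
                 source_id = pose$source_id,
                 walking_frame = FALSE),
            class = "pixel_trajectories")
}

#' Re-express pixel coordinates in the walking frame
#'
#' Changes the pixel coordinate system so that positive vertical points up
#' and positive horizontal points in the direction of travel. For a
#' left-side view the origin moves to the lower-right image corner
#' (`x' = width - x`, `y' = height - y`); for a right-side view to the
#' lower-left corner (`x' = x`, `y' = height - y`). All downstream
#' analyses are invariant to where the origin sits. Applying the transform
#' twice restores the original raw-image coordinates (involution).
#'
#' @param px A `pixel_trajectories` object (or a [pose_sequence()], which
#'   is converted first).
#' @param confidence_threshold Passed to [as_pixel_trajectories()] when a
#'   pose sequence is given.
#' @return A `pixel_trajectories` object with `walking_frame` toggled.
#' @export
to_walking_frame <- function(px, confidence_threshold = 0) {
  if (inherits(px, "pose_sequence"))
    px <- as_pixel_trajectories(px, confidence_threshold)
  stopifnot(inherits(px, "pixel_trajectories"))
  w <- px$image_size[1]; h <- px$image_size[2]
  if (px$camera_side == "left") px$x <- w - px$x
  px$y <- h - px$y
  px$walking_frame <- !px$walking_frame
  px
}

#' Correct left/right limb identity switches
#'
#' Pose estimators intermittently exchange the left/right labels of the
#' leg keypoints (hip, knee, ankle, heel, big toe, small toe). For each
#' frame the keep-vs-swap assignment is chosen to minimize the summed
#' frame-to-frame displacement of both legs' ankle and knee points
#' relative to the previous corrected frame. Two passes are run — forward
#' from the first frame with valid leg keypoints, and backward from the
#' last — and the solution with the lower total displacement is kept, so
#' an ambiguous first frame cannot lock in a globally flipped labelling.
#'
#' Frames where both legs' keypoints collapse onto one leg (left and right
#' ankles closer than `eps_px` with both confident) are detected and the
#' lower-confidence leg's keypoints are marked missing.
#'
#' @param px A `pixel_trajectories` object.
#' @param eps_px Pixel distance below which confident left and right
#'   ankles are considered to sit on the same leg (default 5).
#' @return `px` with corrected labels, plus attribute `"swap_report"`: a
#'   data frame with columns `frame_index` and `action`
#'   (`"swapped"` or `"same_leg_dropped"`) listing every altered frame.
#' @export
correct_limb_swaps <- function(px, eps_px = 5) {
  stopifnot(inherits(px, "pixel_trajectories"))
  n <- nrow(px$x)
  report <- data.frame(frame_index = integer(), action = character())
  if (n >= 2L) {
    fwd <- .swap_pass(px, seq_len(n))
    bwd_dec <- .swap_pass(px, rev(seq_len(n)))
    bwd <- list(swap = bwd_dec$swap, cost = bwd_dec$cost)
    pick <- if (bwd$cost < fwd$cost - 1e-9) bwd$swap else fwd$swap
    if (any(pick)) {
      px <- .apply_swaps(px, which(pick))
      report <- rbind(report, data.frame(frame_index = which(pick),
                                         action = "swapped"))
    }
  }
  # same-leg collapse: both confident ankles nearly coincident
  dal <- sqrt((px$x[, "ankle_l"] - px$x[, "ankle_r"])^2 +
              (px$y[, "ankle_l"] - px$y[, "ankle_r"])^2)
  same <- which(!is.na(dal) & dal < eps_px)
  if (length(same)) {
    for (i in same) {
      conf_l <- mean(px$conf[i, leg_keypoints("l")])
      conf_r <- mean(px$conf[i, leg_keypoints("r")])
      drop <- leg_keypoints(if (conf_l <= conf_r) "l" else "r")
      px$x[i, drop] <- NA_real_
      px$y[i, drop] <- NA_real_
      px$conf[i, drop] <- 0
    }
    report <- rbind(report, data.frame(frame_index = same,
                                       action = "same_leg_dropped"))
  }
  report <- report[order(report$frame_index), , drop = FALSE]
  rownames(report) <- NULL
  attr(px, "swap_report") <- report
  px
}

# One keep-vs-swap labelling pass over frames in the given order.
# Returns the per-frame swap decision (in original frame order) and the
# total displacement cost of the resulting labelling.
.swap_pass <- function(px, order_idx) {
  pts_l <- c("ankle_l", "knee_l"); pts_r <- c("ankle_r", "knee_r")
  n <- nrow(px$x)
  swap <- logical(n)
  prev <- NULL  # 4 x 2 matrix: rows ankle_l, knee_l, ankle_r, knee_r
  total <- 0
  for (i in order_idx) {
    cur_l <- cbind(px$x[i, pts_l], px$y[i, pts_l])
    cur_r <- cbind(px$x[i, pts_r], px$y[i, pts_r])
    if (is.null(prev)) {
      if (any(stats::complete.cases(rbind(cur_l, cur_r))))
        prev <- rbind(cur_l, cur_r)
      next
    }
    cost_keep <- .disp_cost(rbind(cur_l, cur_r), prev)
    cost_swap <- .disp_cost(rbind(cur_r, cur_l), prev)
    if (!is.na(cost_swap) && !is.na(cost_keep) && cost_swap < cost_keep) {
      swap[i] <- TRUE
      tmp <- cur_l; cur_l <- cur_r; cur_r <- tmp
      total <- total + cost_swap
    } else if (!is.na(cost_keep)) {
      total <- total + cost_keep
    }
    upd <- rbind(cur_l, cur_r)
    ok <- stats::complete.cases(upd)
    prev[ok, ] <- upd[ok, ]
  }
  list(swap = swap, cost = total)
}

.disp_cost <- function(cur, prev) {
  d <- sqrt(rowSums((cur - prev)^2))
  if (all(is.na(d))) return(NA_real_)
  sum(d, na.rm = TRUE)
}

.apply_swaps <- function(px, frames) {
  l <- leg_keypoints("l"); r <- leg_keypoints("r")
  for (f in c("x", "y", "conf")) {
    tmp <- px[[f]][frames, l, drop = FALSE]
    px[[f]][frames, l] <- px[[f]][frames, r, drop = FALSE]
    px[[f]][frames, r] <- tmp
  }
  px
}

#' Fill short gaps by linear interpolation
#'
#' Runs of at most `max_gap` consecutive missing samples bounded by valid
#' samples on both sides are linearly interpolated; longer runs and runs
#' touching the record boundary remain missing. At 25 Hz the default of 2
#' frames corresponds to gaps spanning up to 0.12 s between valid anchors.
#' Valid samples are never altered.
#'
#' @param x A numeric vector with `NA` marking missing samples, or a
#'   `pixel_trajectories` object (all keypoint coordinate series are
#'   filled).
#' @param max_gap Maximum gap length, in samples, to interpolate.
#' @param ... Unused.
#' @return Object of the same type with short gaps filled.
#' @export
fill_gaps <- function(x, max_gap = 2, ...) UseMethod("fill_gaps")

#' @rdname fill_gaps
#' @export
fill_gaps.default <- function(x, max_gap = 2, ...) {
  if (all(is.na(x))) {
    warning("series is entirely missing; returned unchanged")
    return(x)
  }
  as.numeric(zoo::na.approx(x, maxgap = max_gap, na.rm = FALSE))
}

#' @rdname fill_gaps
#' @export
fill_gaps.pixel_trajectories <- function(x, max_gap = 2, ...) {
  for (k in colnames(x$x)) {
    if (all(is.na(x$x[, k]))) next  # keypoint never observed: leave silently
    x$x[, k] <- fill_gaps.default(x$x[, k], max_gap)
    x$y[, k] <- fill_gaps.default(x$y[, k], max_gap)
  }
  x
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth design forward and backward (zero net
#' phase; the magnitude response is squared, so a 4th-order design acts as
#' an 8th-order magnitude filter). Edges are handled by odd reflection
#' padding with steady-state initial filter conditions, so a constant
#' series passes through unchanged (DC gain exactly 1). Missing samples
#' split the series into contiguous valid spans that are filtered
#' independently; spans shorter than the warm-up length (3 x order
#' samples) are left unfiltered with a warning.
#'
#' @param x Numeric vector (possibly with `NA`), or a `pixel_trajectories`
#'   object.
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @param cutoff Cut-off frequency in Hz (default 5).
#' @param order Filter order of the one-way design (default 4).
#' @param ... Unused.
#' @return Filtered object of the same type.
#' @export
lowpass_filter <- function(x, fs, cutoff = 5, order = 4, ...)
  UseMethod("lowpass_filter")

#' @rdname lowpass_filter
#' @export
lowpass_filter.default <- function(x, fs, cutoff = 5, order = 4, ...) {
  stopifnot(fs > 0, cutoff > 0, cutoff < fs / 2)
  coef <- signal::butter(order, cutoff / (fs / 2), type = "low")
  warm <- 3L * order
  out <- x
  runs <- .valid_runs(x)
  for (r in runs) {
    if (length(r) <= warm) {
      warning("span of ", length(r),
              " samples is shorter than the filter warm-up; left unfiltered")
      next
    }
    out[r] <- .filtfilt_reflect(coef$b, coef$a, x[r], pad = warm)
  }
  out
}

#' @rdname lowpass_filter
#' @export
lowpass_filter.pixel_trajectories <- function(x, fs = x$frame_rate,
                                              cutoff = 5, order = 4, ...) {
  for (k in colnames(x$x)) {
    if (all(is.na(x$x[, k]))) next
    x$x[, k] <- lowpass_filter.default(x$x[, k], fs, cutoff, order)
    x$y[, k] <- lowpass_filter.default(x$y[, k], fs, cutoff, order)
  }
  x
}

.valid_runs <- function(x) {
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mapply(function(s, e, v) if (v) s:e else NULL,
         starts, ends, r$values, SIMPLIFY = FALSE)[r$values]
}

# Forward-backward IIR filtering with odd reflection padding and
# steady-state initial conditions (transposed direct form II).
.filtfilt_reflect <- function(b, a, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1L)
  pre <- 2 * x[1] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  xx <- c(pre, x, post)
  zi <- .lfilter_zi(b, a)
  y <- .df2t_filter(b, a, xx, zi * xx[1])
  y <- rev(.df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(p + 1L):(p + n)]
}

# Steady-state state vector of the transposed direct-form-II filter for a
# unit-step input (the standard lfilter_zi construction).
.lfilter_zi <- function(b, a) {
  m <- length(a)
  comp <- matrix(0, m - 1L, m - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (m > 2L) comp[cbind(2:(m - 1L), 1:(m - 2L))] <- 1
  IminusA <- diag(m - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

.df2t_filter <- function(b, a, x, z) {
  n <- length(x); m <- length(b)
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (m > 2L)
      z[1:(m - 2L)] <- b[2:(m - 1L)] * x[i] + z[2:(m - 1L)] -
        a[2:(m - 1L)] * y[i]
    z[m - 1L] <- b[m] * x[i] - a[m] * y[i]
  }
  y
}

#' Compute a pixel-to-meter scaling calibration
#'
#' The scaling factor `s` (m/px) is the known reference distance divided by
#' the horizontal pixel length between two landmarks at the walking depth
#' (e.g., the midpoints of two floor-tape strips at either end of the
#' walkway). The default reference distance of 6.30 m is the walkway tape
#' separation of the public dataset this workflow was validated on.
#'
#' @param point_a_px,point_b_px Pixel coordinates `c(x, y)` of the two
#'   reference landmarks.
#' @param reference_distance_m Known metric distance between them
#'   (default 6.30).
#' @return Object of class `scaling_calibration`: list with
#'   `reference_distance`, `reference_pixel_length` and `s` (m/px).
#' @export
compute_scaling <- function(point_a_px, point_b_px,
                            reference_distance_m = 6.30) {
  stopifnot(reference_distance_m > 0)
  px_len <- abs(point_a_px[1] - point_b_px[1])
  if (px_len == 0) stop("zero horizontal pixel separation between landmarks")
  structure(list(reference_distance = reference_distance_m,
                 reference_pixel_length = px_len,
                 s = reference_distance_m / px_len),
            class = "scaling_calibration")
}

#' Convert pixel trajectories to metric trajectories
#'
#' Multiplies every coordinate by the scaling factor `s` and assembles a
#' trajectory set with canonical point names. The pose-specific pelvis
#' reference is the midhip keypoint and the trunk reference is the neck
#' keypoint; `toe_l`/`toe_r` alias the big-toe keypoints so the pose and
#' marker paths share one naming scheme.
#'
#' @param px A `pixel_trajectories` object in the walking frame.
#' @param scaling A [compute_scaling()] calibration (or a number, taken as
#'   `s` in m/px).
#' @return A `trajectory_set`: list with `time` (s), `x`, `y`
#'   (`n x points` matrices, meters), `sampling_rate`, `provenance`.
#' @export
dimensionalize <- function(px, scaling) {
  stopifnot(inherits(px, "pixel_trajectories"))
  s <- if (inherits(scaling, "scaling_calibration")) scaling$s
       else as.numeric(scaling)
  stopifnot(is.finite(s), s > 0)
  x <- px$x * s
  y <- px$y * s
  add <- function(m, new, from) {m <- cbind(m, m[, from, drop = FALSE]);
    colnames(m)[ncol(m) - length(from) + seq_along(from)] <- new; m}
  x <- add(x, c("pelvis", "trunk", "toe_l", "toe_r"),
           c("midhip", "neck", "bigtoe_l", "bigtoe_r"))
  y <- add(y, c("pelvis", "trunk", "toe_l", "toe_r"),
           c("midhip", "neck", "bigtoe_l", "bigtoe_r"))
  n <- nrow(x)
  structure(list(time = (seq_len(n) - 1L) / px$frame_rate,
                 x = x, y = y,
                 sampling_rate = px$frame_rate,
                 provenance = paste0("pose_", px$camera_side)),
            class = "trajectory_set",
            swap_report = attr(px, "swap_report"))
}

#' Build a trajectory set from a marker table
#'
#' Assembles the canonical point set from marker columns. The pelvis
#' reference is the midpoint of the left/right ASIS and PSIS markers; the
#' trunk reference is the C7 marker.
#'
#' @param markers A `marker_table` from [read_marker_csv()].
#' @return A `trajectory_set` with provenance `"mocap"`.
#' @export
marker_trajectories <- function(markers) {
  rate <- attr(markers, "sampling_rate")
  if (is.null(rate)) {
    dt <- diff(markers$time)
    rate <- 1 / dt[1]
  }
  base <- required_markers()
  x <- sapply(base, function(m) markers[[paste0(m, "_x")]])
  y <- sapply(base, function(m) markers[[paste0(m, "_y")]])
  pelvis_x <- rowMeans(x[, c("asis_l", "asis_r", "psis_l", "psis_r")])
  pelvis_y <- rowMeans(y[, c("asis_l", "asis_r", "psis_l", "psis_r")])
  x <- cbind(x, pelvis = pelvis_x, trunk = x[, "c7"])
  y <- cbind(y, pelvis = pelvis_y, trunk = y[, "c7"])
  structure(list(time = markers$time, x = x, y = y,
                 sampling_rate = rate, provenance = "mocap"),
            class = "trajectory_set")
}

#' Default processing configuration
#'
#' Tunable parameters of the video-processing chain with their defaults:
#' 5 Hz cut-off, 4th-order zero-phase Butterworth, 2-frame gap limit,
#' missing-keypoint confidence threshold of 0, 5 px same-leg collapse
#' tolerance, 6.30 m scaling reference distance, and event-detector
#' settings (0.4 s minimum peak separation, prominence fraction 0.25,
#' 0.4 s boundary flagging margin).
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(cutoff_hz = 5, filter_order = 4, max_gap_frames = 2,
              confidence_threshold = 0, eps_same_leg_px = 5,
              reference_distance_m = 6.30,
              min_period_s = 0.4, prominence_frac = 0.25,
              boundary_s = 0.4, n_cycle_samples = 101L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full pixel-to-metric preprocessing chain
#'
#' Applies, in order: walking-frame convention, limb-swap correction,
#' gap filling, zero-phase low-pass filtering, and scaling to meters.
#'
#' @param pose A [pose_sequence()].
#' @param scaling A [compute_scaling()] calibration (or `s` in m/px).
#' @param config Configuration list from [default_config()].
#' @return A `trajectory_set` (attribute `"swap_report"` carries the
#'   limb-swap correction log).
#' @export
preprocess_pose <- function(pose, scaling, config = default_config()) {
  px <- to_walking_frame(pose, config$confidence_threshold)
  px <- correct_limb_swaps(px, eps_px = config$eps_same_leg_px)
  px <- fill_gaps(px, max_gap = config$max_gap_frames)
  px <- lowpass_filter(px, cutoff = config$cutoff_hz,
                       order = config$filter_order)
  dimensionalize(px, scaling)
}
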