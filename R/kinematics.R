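#' Per-frame sagittal hip, knee and ankle angles
#'
#' Two-dimensional joint angles from the hip, knee, ankle and (big) toe
#' points of each leg, in degrees:
#' \itemize{
#'   \item hip: signed angle of the thigh vector (hip to knee) from
#'     vertical-down; 0 deg when the thigh is vertical, flexion (knee
#'     forward of hip) positive, extension negative;
#'   \item knee: signed angle between the thigh vector and the shank
#'     vector (knee to ankle); 0 deg when colinear, flexion (ankle behind
#'     the thigh line) positive;
#'   \item ankle: signed angle of the foot vector (ankle to toe) relative
#'     to the line perpendicular to the shank; 0 deg when the foot is
#'     perpendicular to the shank (horizontal when the shank is vertical),
#'     dorsiflexion (toe up) positive, plantarflexion negative.
#' }
#' Angles are invariant to coordinate translation and uniform scaling.
#' Frames with a missing defining point yield `NA` for that angle.
#'
#' @param ts A `trajectory_set` in the walking frame (x along travel, y
#'   up).
#' @return Data frame of class `joint_angles` with columns `time`, `leg`
#'   (`"left"`/`"right"`), `hip`, `knee`, `ankle` (degrees); attribute
#'   `sampling_rate`.
#' @export
joint_angle_series <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  deg <- 180 / pi
  out <- list()
  for (leg in c("left", "right")) {
    s <- if (leg == "left") "l" else "r"
    hx <- ts$x[, paste0("hip_", s)]; hy <- ts$y[, paste0("hip_", s)]
    kx <- ts$x[, paste0("knee_", s)]; ky <- ts$y[, paste0("knee_", s)]
    ax <- ts$x[, paste0("ankle_", s)]; ay <- ts$y[, paste0("ankle_", s)]
    tx <- ts$x[, paste0("toe_", s)]; ty <- ts$y[, paste0("toe_", s)]
    # thigh and shank angles from vertical-down, positive forward
    thigh <- atan2(kx - hx, -(ky - hy)) * deg
    shank <- atan2(ax - kx, -(ay - ky)) * deg
    foot <- atan2(ty - ay, tx - ax) * deg  # from horizontal, toe-up positive
    hip <- thigh
    knee <- .wrap_deg(thigh - shank)
    ankle <- .wrap_deg(foot - shank)
    out[[leg]] <- data.frame(time = ts$time, leg = leg,
                             hip = hip, knee = knee, ankle = ankle)
  }
  ja <- rbind(out$left, out$right)
  rownames(ja) <- NULL
  class(ja) <- c("joint_angles", "data.frame")
  attr(ja, "sampling_rate") <- ts$sampling_rate
  ja
}

.wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Time-normalize joint angles to the gait cycle
#'
#' Cuts the per-frame angle series into strides (same-side heel-strike to
#' heel-strike), linearly resamples each stride onto a fixed percentage
#' grid (0-100% of the gait cycle; 101 points by default, the field
#' convention), and forms the ensemble mean and SD across strides per leg
#' and joint. Endpoint values are preserved exactly by the resampling.
#'
#' @param angles A `joint_angles` data frame from [joint_angle_series()].
#' @param events A `gait_events` data frame.
#' @param ts Optional `trajectory_set`; when given, each stride is also
#'   tagged with its mean anterior-posterior trunk position (for
#'   walkway-position binning).
#' @param n_samples Number of cycle grid points (default 101).
#' @param exclude_boundary Skip strides bounded by a boundary-flagged
#'   heel-strike (default `TRUE`).
#' @return Object of class `angle_cycles`: per leg, matrices `hip`,
#'   `knee`, `ankle` of size `strides x n_samples`, lists `mean` and `sd`
#'   of per-joint 101-point profiles, vectors `walkway` and `hs_time` per
#'   stride. Attribute `cycle_pct` holds the percentage grid.
#' @export
normalize_strides <- function(angles, events, ts = NULL, n_samples = 101L,
                              exclude_boundary = TRUE) {
  stopifnot(inherits(angles, "joint_angles"))
  ev <- as.data.frame(events)
  pct <- seq(0, 100, length.out = n_samples)
  out <- list()
  for (leg in c("left", "right")) {
    hs <- ev[ev$event == "heel_strike" & ev$side == leg, ]
    hs <- hs[order(hs$time_s), ]
    if (exclude_boundary) {
      # a stride is kept when both bounding heel-strikes are interior
      keep_start <- !hs$boundary[-nrow(hs)] & !hs$boundary[-1L]
    } else keep_start <- rep(TRUE, max(nrow(hs) - 1L, 0L))
    a <- angles[angles$leg == leg, ]
    mats <- list(hip = NULL, knee = NULL, ankle = NULL)
    walkway <- numeric(); hs_time <- numeric()
    if (nrow(hs) >= 2L) for (k in seq_len(nrow(hs) - 1L)) {
      if (!keep_start[k]) next
      t0 <- hs$time_s[k]; t1 <- hs$time_s[k + 1L]
      grid <- seq(t0, t1, length.out = n_samples)
      for (j in names(mats)) {
        ok <- !is.na(a[[j]])
        if (sum(ok) < 2L) {prof <- rep(NA_real_, n_samples)} else
          prof <- stats::approx(a$time[ok], a[[j]][ok], xout = grid)$y
        mats[[j]] <- rbind(mats[[j]], prof)
      }
      hs_time <- c(hs_time, t0)
      walkway <- c(walkway, if (!is.null(ts)) {
        inb <- ts$time >= t0 & ts$time <= t1
        mean(ts$x[inb, "trunk"], na.rm = TRUE)
      } else NA_real_)
    }
    if (is.null(mats$hip)) {
      warning("no complete strides on ", leg, " side")
      mats <- lapply(mats, function(z) matrix(numeric(), 0L, n_samples))
    }
    mats <- lapply(mats, function(m) {rownames(m) <- NULL; m})
    out[[leg]] <- list(
      hip = mats$hip, knee = mats$knee, ankle = mats$ankle,
      mean = lapply(mats, function(m) if (nrow(m)) colMeans(m)
                    else rep(NA_real_, n_samples)),
      sd = lapply(mats, function(m) if (nrow(m) > 1L) apply(m, 2, stats::sd)
                  else rep(NA_real_, n_samples)),
      walkway = walkway, hs_time = hs_time)
  }
  structure(out, class = "angle_cycles", cycle_pct = pct)
}
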