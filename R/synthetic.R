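#' Specification of a synthetic walking bout
#'
#' Parameters of the forward-kinematic sagittal walker and its recording
#' setup. Defaults emulate a typical overground laboratory bout: a ~5 m
#' walk at 1.0 m/s (step time 0.6 s, step length 0.6 m), video at 25 Hz
#' and 960x540 px from a sagittal camera about 3.3 m from the walking
#' plane at 1.3 m height, with a simultaneous 100 Hz marker stream from
#' the same underlying motion. The walkway midpoint is the world origin.
#'
#' The walker's pelvis translates at the gait speed while periodic
#' sinusoidal joint-angle profiles (two legs half a stride out of phase)
#' drive the leg keypoints through forward kinematics. The hip-profile
#' amplitude is calibrated internally so that the emergent step length
#' equals `step_length`; an unreachable step length given the segment
#' lengths raises a validation error at simulation time.
#'
#' @param step_time Step duration per side, s (stride = 2 steps).
#' @param step_length Step length, m. Gait speed is
#'   `step_length / step_time`.
#' @param bout_length Walkway length covered, m.
#' @param frame_rate Video frame rate, Hz.
#' @param marker_rate Marker (reference-system) sampling rate, Hz.
#' @param image_size `c(width, height)` px.
#' @param thigh,shank,foot Segment lengths, m.
#' @param hip_mean Mean hip angle over the cycle, deg.
#' @param hip_amp2,hip_phase2 Second-harmonic amplitude (deg) and phase
#'   (cycle fraction) of the hip profile. The second harmonic skews the
#'   relative ankle trajectory the way ground contact does in real gait
#'   (slow backward drift in stance, fast forward swing), placing toe-off
#'   about 60% of the cycle after heel-strike so a double-support phase
#'   exists.
#' @param knee_mean,knee_amp,knee_phase Knee flexion profile: mean and
#'   amplitude (deg) of a cosine peaking at cycle fraction `knee_phase`.
#' @param ankle_mean,ankle_amp,ankle_phase Ankle dorsiflexion profile.
#' @param camera List: `mode` (`"orthographic"` or `"pinhole"`), `side`
#'   (`"left"`/`"right"`), `distance` (m), `height` (m), `focal` (px).
#' @param leg_offset_m Mediolateral half-distance between the legs, m;
#'   gives the two legs different depths in pinhole mode (the source of
#'   parallax in step-length estimates).
#' @param defects List of defect rates for [inject_defects()]:
#'   `noise_sd` (px), `gap_rate`, `swap_rate`, `false_person_rate` (per
#'   frame), `gap_len` (range of gap lengths in frames).
#' @param seed Integer seed used by [inject_defects()].
#' @return List of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(step_time = 0.6, step_length = 0.6,
                                bout_length = 5, frame_rate = 25,
                                marker_rate = 100,
                                image_size = c(960L, 540L),
                                thigh = 0.41, shank = 0.42, foot = 0.20,
                                hip_mean = 8,
                                hip_amp2 = 6, hip_phase2 = 0.05,
                                knee_mean = 32, knee_amp = 30,
                                knee_phase = 0.70,
                                ankle_mean = 0, ankle_amp = 12,
                                ankle_phase = 0.45,
                                camera = list(mode = "orthographic",
                                              side = "left",
                                              distance = 3.3, height = 1.3,
                                              focal = 495),
                                leg_offset_m = 0.09,
                                defects = list(noise_sd = 0, gap_rate = 0,
                                               swap_rate = 0,
                                               false_person_rate = 0,
                                               gap_len = c(1L, 2L)),
                                seed = 1L) {
  stopifnot(step_time > 0, step_length > 0, bout_length > 0,
            frame_rate > 0, marker_rate > 0, thigh > 0, shank > 0, foot > 0,
            camera$mode %in% c("orthographic", "pinhole"),
            camera$side %in% c("left", "right"),
            camera$distance > 0, camera$focal > 0)
  def <- list(noise_sd = 0, gap_rate = 0, swap_rate = 0,
              false_person_rate = 0, gap_len = c(1L, 2L))
  def[names(defects)] <- defects
  structure(list(step_time = step_time, step_length = step_length,
                 gait_speed = step_length / step_time,
                 stride_time = 2 * step_time,
                 bout_length = bout_length, frame_rate = frame_rate,
                 marker_rate = marker_rate, image_size = as.integer(image_size),
                 thigh = thigh, shank = shank, foot = foot,
                 hip_mean = hip_mean, hip_amp2 = hip_amp2,
                 hip_phase2 = hip_phase2, knee_mean = knee_mean,
                 knee_amp = knee_amp, knee_phase = knee_phase,
                 ankle_mean = ankle_mean, ankle_amp = ankle_amp,
                 ankle_phase = ankle_phase,
                 camera = camera, leg_offset_m = leg_offset_m,
                 defects = def, seed = as.integer(seed)),
            class = "synthetic_gait_spec")
}

# Joint-angle profiles as functions of cycle fraction u (0 = peak hip
# flexion), degrees.
.profile_hip <- function(u, spec, hip_amp)
  spec$hip_mean + hip_amp * cos(2 * pi * u) +
    spec$hip_amp2 * cos(4 * pi * (u - spec$hip_phase2))
.profile_knee <- function(u, spec)
  spec$knee_mean + spec$knee_amp * cos(2 * pi * (u - spec$knee_phase))
.profile_ankle <- function(u, spec)
  spec$ankle_mean + spec$ankle_amp * cos(2 * pi * (u - spec$ankle_phase))

# Anterior-posterior ankle position relative to the pelvis at cycle
# fraction u (meters).
.rel_ankle_ap <- function(u, spec, hip_amp) {
  a <- .profile_hip(u, spec, hip_amp) * pi / 180
  k <- .profile_knee(u, spec) * pi / 180
  spec$thigh * sin(a) + spec$shank * sin(a - k)
}

# Cycle fractions of heel-strike (max) and toe-off (min) of the relative
# AP ankle trajectory, refined from a fine grid.
.event_phases <- function(spec, hip_amp) {
  u <- seq(0, 1, length.out = 4001L)[-4001L]
  r <- .rel_ankle_ap(u, spec, hip_amp)
  refine <- function(u0, f) {
    stats::optimize(function(z) f * .rel_ankle_ap(z %% 1, spec, hip_amp),
                    lower = u0 - 0.01, upper = u0 + 0.01)$minimum %% 1
  }
  list(hs = refine(u[which.max(r)], -1), to = refine(u[which.min(r)], 1))
}

# Emergent step length for a given hip amplitude: leading minus trailing
# relative ankle position at heel-strike (legs half a cycle apart).
.emergent_step_length <- function(spec, hip_amp) {
  ph <- .event_phases(spec, hip_amp)
  .rel_ankle_ap(ph$hs, spec, hip_amp) -
    .rel_ankle_ap((ph$hs - 0.5) %% 1, spec, hip_amp)
}

.calibrate_hip_amp <- function(spec) {
  f <- function(a) .emergent_step_length(spec, a) - spec$step_length
  lo <- 2; hi <- 55
  if (f(hi) < 0 || f(lo) > 0)
    stop("step_length ", spec$step_length,
         " m is not reachable with the given segment lengths and profiles")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Leg keypoint offsets relative to the pelvis at cycle fraction u.
# Returns a matrix with rows knee, ankle, toe, heel and columns dx, dy.
.leg_offsets <- function(u, spec, hip_amp) {
  d2r <- pi / 180
  a <- .profile_hip(u, spec, hip_amp) * d2r        # thigh from vertical-down
  k <- .profile_knee(u, spec) * d2r                # knee flexion
  b <- .profile_ankle(u, spec) * d2r               # ankle dorsiflexion
  as_ <- a - k                                     # shank from vertical-down
  knee <- c(spec$thigh * sin(a), -spec$thigh * cos(a))
  ankle <- knee + c(spec$shank * sin(as_), -spec$shank * cos(as_))
  fdir <- c(cos(as_ + b), sin(as_ + b))            # foot direction
  toe <- ankle + spec$foot * fdir
  heel <- ankle - 0.35 * spec$foot * fdir
  rbind(knee = knee, ankle = ankle, toe = toe, heel = heel)
}

# Full 3D skeleton at time t: world x (travel), y (up), z (lateral toward
# the person's left, so a left-side camera sees z > 0 as nearer).
.skeleton <- function(t, spec, hip_amp, hs_phase) {
  v <- spec$gait_speed
  px <- -spec$bout_length / 2 + v * t
  h_hip <- spec$thigh + spec$shank + 0.05
  u_l <- (hs_phase + t / spec$stride_time) %% 1
  u_r <- (u_l + 0.5) %% 1
  leg <- function(u, z) {
    o <- .leg_offsets(u, spec, hip_amp)
    list(hip = c(px, h_hip, z),
         knee = c(px + o["knee", 1], h_hip + o["knee", 2], z),
         ankle = c(px + o["ankle", 1], h_hip + o["ankle", 2], z),
         bigtoe = c(px + o["toe", 1], h_hip + o["toe", 2], z),
         smalltoe = c(px + 0.92 * o["toe", 1] + 0.08 * o["ankle", 1],
                      h_hip + 0.92 * o["toe", 2] + 0.08 * o["ankle", 2], z),
         heel = c(px + o["heel", 1], h_hip + o["heel", 2], z))
  }
  L <- leg(u_l, +spec$leg_offset_m)
  R <- leg(u_r, -spec$leg_offset_m)
  up <- function(dx, dy, z = 0) c(px + dx, h_hip + dy, z)
  list(nose = up(0.06, 0.70), neck = up(0.00, 0.55),
       shoulder_r = up(0.00, 0.50, -0.15), elbow_r = up(0.02, 0.26, -0.17),
       wrist_r = up(0.04, 0.04, -0.17),
       shoulder_l = up(0.00, 0.50, 0.15), elbow_l = up(0.02, 0.26, 0.17),
       wrist_l = up(0.04, 0.04, 0.17),
       midhip = c(px, h_hip, 0),
       hip_r = R$hip, knee_r = R$knee, ankle_r = R$ankle,
       hip_l = L$hip, knee_l = L$knee, ankle_l = L$ankle,
       eye_r = up(0.08, 0.73, -0.03), eye_l = up(0.08, 0.73, 0.03),
       ear_r = up(0.02, 0.71, -0.06), ear_l = up(0.02, 0.71, 0.06),
       bigtoe_l = L$bigtoe, smalltoe_l = L$smalltoe, heel_l = L$heel,
       bigtoe_r = R$bigtoe, smalltoe_r = R$smalltoe, heel_r = R$heel)
}

# Project a world point c(x, y, z) to raw image pixels (origin upper
# left). A left-side camera sees travel as right-to-left in the image.
.project_point <- function(p, spec) {
  cam <- spec$camera
  cx <- spec$image_size[1] / 2; cy <- spec$image_size[2] / 2
  z_cam <- if (cam$mode == "pinhole") {
    if (cam$side == "left") cam$distance - p[3] else cam$distance + p[3]
  } else cam$distance
  sgn <- if (cam$side == "left") -1 else 1
  u <- cx + sgn * cam$focal * p[1] / z_cam
  v <- cy - cam$focal * (p[2] - cam$height) / z_cam
  c(u, v)
}

#' Simulate a ground-truthed walking bout
#'
#' Generates a synchronized pair of recordings of one synthetic walking
#' bout — a pose sequence (pixel keypoints through the camera model) and a
#' marker table (metric marker positions at the marker rate) — together
#' with exact ground truth: event times (defined at the programmed
#' extrema of the relative anterior-posterior ankle trajectory, refined on
#' the continuous model), a per-step spatiotemporal table, 101-point
#' joint-angle cycle profiles, and the scaling landmarks (floor-tape
#' midpoints) in pixel coordinates.
#'
#' The first left heel-strike occurs at t = 0, so with the default 0.6 s
#' step time and 25 Hz frame rate every true event falls exactly on a
#' video frame.
#'
#' @param spec A [synthetic_gait_spec()].
#' @return List of class `gait_simulation`: `pose` (a [pose_sequence()]),
#'   `markers` (a `marker_table`), `truth` (events, step table, angle
#'   profiles, calibrated hip amplitude, tape pixel positions), `spec`.
#' @export
simulate_gait <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gait_spec"))
  hip_amp <- .calibrate_hip_amp(spec)
  ph <- .event_phases(spec, hip_amp)
  hs_phase <- ph$hs  # left-leg cycle starts so that HS is at t = 0
  dur <- spec$bout_length / spec$gait_speed
  T_str <- spec$stride_time

  # --- ground-truth events -------------------------------------------
  ev <- list()
  add_ev <- function(side, event, t0) {
    tt <- seq(t0, dur, by = T_str)
    tt <- tt[tt >= 0 & tt <= dur]
    if (length(tt))
      data.frame(side = side, event = event, time_s = tt,
                 frame_index = round(tt * spec$frame_rate) + 1L,
                 boundary = FALSE)
  }
  stance_frac <- (ph$to - ph$hs) %% 1
  ev <- rbind(add_ev("left", "heel_strike", 0),
              add_ev("right", "heel_strike", spec$step_time),
              add_ev("left", "toe_off", stance_frac * T_str),
              add_ev("right", "toe_off",
                     (stance_frac * T_str + spec$step_time) %% T_str))
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")

  # --- ground-truth step table ---------------------------------------
  sl <- .emergent_step_length(spec, hip_amp)
  stance_t <- stance_frac * T_str
  dsup_t <- ((ph$to - ph$hs - 0.5) %% 1) * T_str
  hs <- ev[ev$event == "heel_strike", ]
  truth_steps <- do.call(rbind, lapply(2:nrow(hs), function(k)
    data.frame(side = hs$side[k], hs_time = hs$time_s[k],
               step_time = hs$time_s[k] - hs$time_s[k - 1L],
               stance_time = stance_t, swing_time = T_str - stance_t,
               double_support_time = dsup_t, step_length = sl,
               walkway_position = -spec$bout_length / 2 +
                 spec$gait_speed * hs$time_s[k],
               boundary = FALSE)))
  class(truth_steps) <- c("step_table", "data.frame")

  # --- ground-truth joint-angle cycle profiles (HS-anchored) ---------
  pct <- seq(0, 100, length.out = 101L)
  uu <- (hs_phase + pct / 100) %% 1
  profiles <- list(hip = .profile_hip(uu, spec, hip_amp),
                   knee = .profile_knee(uu, spec),
                   ankle = .profile_ankle(uu, spec))

  # --- marker table (metric, exact) ----------------------------------
  tm <- seq(0, dur, by = 1 / spec$marker_rate)
  mk <- lapply(tm, function(t) .skeleton(t, spec, hip_amp, hs_phase))
  col <- function(name, i) vapply(mk, function(s) s[[name]][i], numeric(1))
  markers <- data.frame(time = tm)
  for (nm in c("ankle_l", "ankle_r", "knee_l", "knee_r", "hip_l", "hip_r",
               "heel_l", "heel_r")) {
    markers[[paste0(nm, "_x")]] <- col(nm, 1)
    markers[[paste0(nm, "_y")]] <- col(nm, 2)
  }
  markers$toe_l_x <- col("bigtoe_l", 1); markers$toe_l_y <- col("bigtoe_l", 2)
  markers$toe_r_x <- col("bigtoe_r", 1); markers$toe_r_y <- col("bigtoe_r", 2)
  # pelvis cluster around the midhip, C7 above it
  mh_x <- col("midhip", 1); mh_y <- col("midhip", 2)
  markers$asis_l_x <- mh_x + 0.12; markers$asis_l_y <- mh_y + 0.02
  markers$asis_r_x <- mh_x + 0.12; markers$asis_r_y <- mh_y + 0.02
  markers$psis_l_x <- mh_x - 0.12; markers$psis_l_y <- mh_y + 0.04
  markers$psis_r_x <- mh_x - 0.12; markers$psis_r_y <- mh_y + 0.04
  markers$c7_x <- col("neck", 1); markers$c7_y <- col("neck", 2) + 0.02
  markers <- structure(markers, class = c("marker_table", "data.frame"),
                       sampling_rate = spec$marker_rate)

  # --- pose sequence through the camera ------------------------------
  tv <- seq(0, dur, by = 1 / spec$frame_rate)
  kp_names <- body25_keypoints()
  xyc <- array(0, dim = c(length(tv), 25L, 3L))
  for (i in seq_along(tv)) {
    sk <- .skeleton(tv[i], spec, hip_amp, hs_phase)
    for (j in seq_along(kp_names)) {
      uv <- .project_point(sk[[kp_names[j]]], spec)
      xyc[i, j, ] <- c(uv, 0.9)
    }
  }
  pose <- pose_sequence(xyc, spec$frame_rate, spec$camera$side,
                        spec$image_size, source_id = "synthetic_walker")

  # --- scaling landmarks: floor tape strips 6.30 m apart, centered ---
  tape_dist <- 6.30
  tape_a <- .project_point(c(-tape_dist / 2, 0, 0), spec)
  tape_b <- .project_point(c(tape_dist / 2, 0, 0), spec)

  structure(list(pose = pose, markers = markers,
                 truth = list(events = ev, steps = truth_steps,
                              profiles = profiles, cycle_pct = pct,
                              hip_amp = hip_amp, step_length = sl,
                              gait_speed = spec$gait_speed,
                              tape_px = list(a = tape_a, b = tape_b),
                              tape_distance_m = tape_dist),
                 spec = spec),
            class = "gait_simulation")
}

#' Inject pose-estimation defects into a pose sequence
#'
#' Degrades a clean pose sequence with the error modes real pose
#' estimators exhibit, at configured per-frame rates, and logs every
#' altered frame so repairs can be audited:
#' \itemize{
#'   \item `noise_sd`: Gaussian pixel noise on every confident keypoint;
#'   \item `gap_rate`: per frame/keypoint probability that a gap starts;
#'     gap lengths drawn uniformly from `gap_len`; dropped keypoints get
#'     confidence 0 and coordinates 0 (the estimator's missing encoding);
#'   \item `swap_rate`: per-frame probability that the left/right leg
#'     keypoint labels are exchanged;
#'   \item `false_person_rate`: per-frame probability that a static
#'     false-positive "person" (a tripod-like detection with 4 confident
#'     keypoints) is added; written out by [write_openpose_json()].
#' }
#'
#' @param pose A [pose_sequence()].
#' @param defects List of rates (see [synthetic_gait_spec()]).
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @return The degraded `pose_sequence` with attributes
#'   `"injection_log"` (list of `noise_frames`, `gaps` data frame,
#'   `swap_frames`, `false_person_frames`) and `"extra_people"`.
#' @export
inject_defects <- function(pose, defects = list(), seed = 1L) {
  stopifnot(inherits(pose, "pose_sequence"))
  def <- list(noise_sd = 0, gap_rate = 0, swap_rate = 0,
              false_person_rate = 0, gap_len = c(1L, 2L))
  def[names(defects)] <- defects
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n <- n_frames(pose)
  log <- list(noise_frames = integer(), gaps = data.frame(
    frame_index = integer(), keypoint = character(), length = integer()),
    swap_frames = integer(), false_person_frames = integer())

  if (def$noise_sd > 0) {
    conf <- pose$xyc[, , "c"]
    nz <- conf > 0
    pose$xyc[, , "x"][nz] <- pose$xyc[, , "x"][nz] +
      stats::rnorm(sum(nz), 0, def$noise_sd)
    pose$xyc[, , "y"][nz] <- pose$xyc[, , "y"][nz] +
      stats::rnorm(sum(nz), 0, def$noise_sd)
    log$noise_frames <- seq_len(n)
  }

  if (def$gap_rate > 0) {
    for (k in seq_len(25L)) {
      starts <- which(stats::runif(n) < def$gap_rate)
      for (s in starts) {
        len <- sample(seq(def$gap_len[1], def$gap_len[2]), 1L)
        idx <- s:min(n, s + len - 1L)
        pose$xyc[idx, k, ] <- 0
        log$gaps <- rbind(log$gaps, data.frame(
          frame_index = s, keypoint = body25_keypoints()[k],
          length = length(idx)))
      }
    }
  }

  if (def$swap_rate > 0) {
    frames <- which(stats::runif(n) < def$swap_rate)
    l <- match(leg_keypoints("l"), body25_keypoints())
    r <- match(leg_keypoints("r"), body25_keypoints())
    for (i in frames) {
      tmp <- pose$xyc[i, l, ]
      pose$xyc[i, l, ] <- pose$xyc[i, r, ]
      pose$xyc[i, r, ] <- tmp
    }
    log$swap_frames <- frames
  }

  extra <- vector("list", n)
  if (def$false_person_rate > 0) {
    frames <- which(stats::runif(n) < def$false_person_rate)
    tripod <- matrix(0, 25L, 3L)
    w <- pose$image_size[1]; h <- pose$image_size[2]
    tripod[c(2L, 9L, 11L, 14L), ] <- cbind(
      c(0.9 * w, 0.9 * w, 0.88 * w, 0.92 * w),
      c(0.4 * h, 0.6 * h, 0.85 * h, 0.85 * h), 0.4)
    for (i in frames) extra[[i]] <- list(tripod)
    log$false_person_frames <- frames
  }

  attr(pose, "injection_log") <- log
  attr(pose, "extra_people") <- extra
  pose
}
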