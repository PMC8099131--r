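pose_ts <- function(hip, knee, ankle, toe) {
  pts <- list(hip_l = hip, knee_l = knee, ankle_l = ankle, toe_l = toe,
              hip_r = hip, knee_r = knee, ankle_r = ankle, toe_r = toe,
              pelvis = c(0, 1), trunk = c(0, 1.5))
  make_ts(c(0, 0.01), lapply(pts, function(p) rbind(p, p)))
}

test_that("joint angles follow the stated sign conventions", {
  # neutral standing: vertical thigh and shank, horizontal foot
  ts <- pose_ts(hip = c(0, 1), knee = c(0, 0.5), ankle = c(0, 0),
                toe = c(0.2, 0))
  a <- joint_angle_series(ts)
  expect_equal(a$hip, rep(0, 4))
  expect_equal(a$knee, rep(0, 4))
  expect_equal(a$ankle, rep(0, 4))

  # thigh tilted forward, leg segments colinear: hip = atan(0.1/0.5)
  dirv <- c(0.1, -0.5) / sqrt(0.26)
  knee <- c(0, 1) + 0.5099 * dirv
  ankle <- knee + 0.5099 * dirv
  ts2 <- pose_ts(c(0, 1), knee, ankle,
                 toe = ankle + 0.2 * c(-dirv[2], dirv[1]))  # shank-perp
  a2 <- joint_angle_series(ts2)
  expect_equal(a2$hip[1], atan(0.1 / 0.5) * 180 / pi, tolerance = 1e-9)
  expect_equal(a2$knee[1], 0, tolerance = 1e-9)
  expect_equal(a2$ankle[1], 0, tolerance = 1e-9)

  # knee flexion: ankle behind the thigh line is positive
  ts3 <- pose_ts(c(0, 1), c(0, 0.5), c(-0.2, 0.1), toe = c(0, 0.05))
  expect_gt(joint_angle_series(ts3)$knee[1], 0)

  # dorsiflexion: toe above the shank perpendicular is positive
  ts4 <- pose_ts(c(0, 1), c(0, 0.5), c(0, 0), toe = c(0.19, 0.06))
  expect_gt(joint_angle_series(ts4)$ankle[1], 0)

  # missing point -> missing angle
  ts5 <- pose_ts(c(0, 1), c(0, 0.5), c(0, 0), toe = c(0.2, 0))
  ts5$x[1, "knee_l"] <- NA
  a5 <- joint_angle_series(ts5)
  expect_true(is.na(a5$hip[a5$leg == "left"][1]))
})

test_that("angles are invariant to translation and uniform scaling", {
  ts <- marker_trajectories(default_sim()$markers)
  a0 <- joint_angle_series(ts)
  ts2 <- ts; ts2$x <- ts2$x * 12 + 5; ts2$y <- ts2$y * 12 + 5
  a2 <- joint_angle_series(ts2)
  expect_equal(a2$hip, a0$hip, tolerance = 1e-9)
  expect_equal(a2$knee, a0$knee, tolerance = 1e-9)
  expect_equal(a2$ankle, a0$ankle, tolerance = 1e-9)
})

test_that("the marker path recovers the programmed joint profiles", {
  sim <- default_sim()
  run <- mocap_run()
  for (leg in c("left", "right")) for (j in c("hip", "knee", "ankle"))
    expect_lt(mae_curves(run$cycles[[leg]]$mean[[j]],
                         sim$truth$profiles[[j]]), 0.5)
})

test_that("stride normalization preserves endpoints and averages correctly", {
  t <- seq(0, 2.4, by = 0.01)
  ang <- data.frame(time = t, leg = "left",
                    hip = sin(2 * pi * t / 1.2) * 20,
                    knee = cos(2 * pi * t / 1.2) * 30 + 30,
                    ankle = sin(4 * pi * t / 1.2) * 10)
  class(ang) <- c("joint_angles", "data.frame")
  ev <- data.frame(side = "left", event = "heel_strike",
                   time_s = c(0, 1.2, 2.4),
                   frame_index = c(1L, 121L, 241L), boundary = FALSE)
  class(ev) <- c("gait_events", "data.frame")
  cyc <- suppressWarnings(  # only the left leg is simulated here
    normalize_strides(ang, ev, exclude_boundary = FALSE))
  expect_equal(nrow(cyc$left$hip), 2L)
  # endpoints match the sampled values exactly
  expect_equal(cyc$left$hip[1, 1], ang$hip[1])
  expect_equal(cyc$left$hip[1, 101], ang$hip[121])
  # two identical strides: SD identically zero, mean equals each stride
  expect_equal(max(abs(cyc$left$sd$hip)), 0, tolerance = 1e-9)
  expect_equal(cyc$left$mean$knee, unname(cyc$left$knee[1, ]),
               tolerance = 1e-9)
  # single stride: mean equals that stride's profile
  ev1 <- ev[1:2, ]
  cyc1 <- suppressWarnings(
    normalize_strides(ang, ev1, exclude_boundary = FALSE))
  expect_equal(nrow(cyc1$left$hip), 1L)
  expect_equal(cyc1$left$mean$hip, unname(cyc1$left$hip[1, ]))
})

test_that("left and right camera views agree on angle profiles", {
  simL <- default_sim()
  spR <- synthetic_gait_spec(camera = list(mode = "orthographic",
                                           side = "right", distance = 3.3,
                                           height = 1.3, focal = 495))
  simR <- simulate_gait(spR)
  scalR <- compute_scaling(simR$truth$tape_px$a, simR$truth$tape_px$b,
                           simR$truth$tape_distance_m)
  runR <- analyze_pose(simR$pose, scalR)
  runL <- default_run()
  for (leg in c("left", "right")) for (j in c("hip", "knee", "ankle"))
    expect_lt(mae_curves(runL$cycles[[leg]]$mean[[j]],
                         runR$cycles[[leg]]$mean[[j]]), 0.2)
})
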