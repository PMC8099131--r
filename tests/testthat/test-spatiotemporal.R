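mk_events <- function(side, event, time_s, boundary = FALSE) {
  df <- data.frame(side = side, event = event, time_s = time_s,
                   frame_index = round(time_s * 100) + 1L,
                   boundary = boundary)
  df <- df[order(df$time_s), ]
  class(df) <- c("gait_events", "data.frame")
  df
}

test_that("step, stance, swing and double-support follow their definitions", {
  ev <- mk_events(
    side = c("left", "right", "left", "left", "right", "left"),
    event = c("heel_strike", "heel_strike", "toe_off", "heel_strike",
              "toe_off", "toe_off"),
    time_s = c(0.0, 0.6, 0.75, 1.21, 1.35, 1.95))
  st <- compute_step_table(ev)
  # right step ends at the right heel-strike 0.6 s after the left one
  expect_equal(st$step_time[st$side == "right" & st$hs_time == 0.6], 0.6)
  # left stance 0.0 -> 0.75; swing 0.75 -> 1.21
  expect_equal(st$stance_time[st$hs_time == 0.0], 0.75)
  expect_equal(st$swing_time[st$hs_time == 1.21], 0.46)
  # double support: right HS at 0.6 to left toe-off at 0.75
  expect_equal(st$double_support_time[st$hs_time == 0.6], 0.15)
})

test_that("step length is the ankle separation at heel-strike", {
  t <- seq(0, 1, by = 0.01)
  n <- length(t)
  ts <- make_ts(t, list(ankle_l = cbind(rep(3.0, n), 0.1),
                        ankle_r = cbind(rep(3.6, n), 0.1),
                        trunk = cbind(rep(3.3, n), 1.4),
                        pelvis = cbind(rep(3.3, n), 0.9)))
  ev <- mk_events(c("left", "right"), c("heel_strike", "heel_strike"),
                  c(0.0, 0.6))
  st <- compute_step_table(ev, ts)
  right <- st[st$side == "right", ]
  expect_equal(right$step_length, 0.6)   # x_ankle_r - x_ankle_l at right HS
  expect_equal(right$walkway_position, 3.3)
})

test_that("stance + swing equals stride time and steps tile the stride", {
  st <- as.data.frame(default_run()$steps)
  for (side in c("left", "right")) {
    sub <- st[st$side == side, ]
    stride <- diff(sub$hs_time)
    # swing ending at HS_k+1 plus stance starting at HS_k spans the stride
    lhs <- sub$stance_time[-nrow(sub)] + sub$swing_time[-1]
    ok <- !is.na(lhs) & !is.na(stride)
    expect_equal(lhs[ok], stride[ok], tolerance = 1e-9)
  }
  # consecutive left and right step times sum to the stride time
  ok <- which(!is.na(st$step_time[-1]) & !is.na(st$step_time[-nrow(st)]))
  pair_sum <- st$step_time[ok + 1L] + st$step_time[ok]
  stride <- st$hs_time[ok + 1L] - c(NA, st$hs_time)[ok]
  keep <- !is.na(stride)
  expect_equal(pair_sum[keep], stride[keep], tolerance = 1e-9)
})

test_that("parameters are invariant under time translation of all events", {
  ev <- default_run()$events
  st0 <- compute_step_table(ev)
  ev2 <- ev; ev2$time_s <- ev2$time_s + 17.3
  st2 <- compute_step_table(ev2)
  for (p in c("step_time", "stance_time", "swing_time",
              "double_support_time"))
    expect_equal(st2[[p]], st0[[p]], tolerance = 1e-9)
})

test_that("participant summary implements gait speed as mean length over mean time", {
  s <- participant_summary(default_run()$steps)
  expect_equal(s$gait_speed, s$step_length$mean / s$step_time$mean)
  # degenerate table with a single full step
  ev <- mk_events(c("left", "right"), c("heel_strike", "heel_strike"),
                  c(0.0, 0.6))
  one <- participant_summary(compute_step_table(ev))
  expect_equal(one$step_time$mean, 0.6)
  expect_equal(one$step_time$n, 1L)
})

test_that("the pipeline recovers the programmed gait speed", {
  sim <- default_sim()
  s <- default_run()$summary
  expect_lt(abs(s$gait_speed - sim$truth$gait_speed), 0.02)
})

test_that("ground-truth step table satisfies the spatiotemporal identities exactly", {
  tr <- default_sim()$truth$steps
  expect_equal(tr$stance_time + tr$swing_time,
               rep(2 * 0.6, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$step_time, rep(0.6, nrow(tr)), tolerance = 1e-12)
  expect_true(all(tr$step_length > 0))
  sm <- participant_summary(tr)
  expect_equal(sm$gait_speed, default_sim()$truth$gait_speed,
               tolerance = 1e-9)
})
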