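make_pose <- function(x, y, conf = NULL, side = "left", fr = 25,
                      size = c(960L, 540L)) {
  n <- nrow(x)
  if (is.null(conf)) conf <- matrix(0.9, n, 25L)
  xyc <- array(0, dim = c(n, 25L, 3L))
  xyc[, , 1] <- x; xyc[, , 2] <- y; xyc[, , 3] <- conf
  pose_sequence(xyc, fr, side, size)
}

test_that("walking-frame convention maps corners correctly and is an involution", {
  x <- matrix(seq(0, 960, length.out = 25), 2, 25, byrow = TRUE)
  x[1, 1] <- 960
  y <- matrix(seq(0, 540, length.out = 25), 2, 25, byrow = TRUE)
  pl <- to_walking_frame(make_pose(x, y, side = "left"))
  expect_equal(unname(pl$x[1, 1]), 0)       # lower-right corner -> origin
  expect_equal(unname(pl$y[1, 1]), 540 - y[1, 1])
  pr <- to_walking_frame(make_pose(x, y, side = "right"))
  expect_equal(unname(pr$x[1, ]), x[1, ])   # x unchanged for right view
  expect_equal(unname(pr$y[1, ]), 540 - y[1, ])
  # involution: applying twice restores the raw pixel x
  pl2 <- to_walking_frame(to_walking_frame(make_pose(x, y, side = "left")))
  expect_equal(unname(pl2$x), unname(x))
  expect_false(pl2$walking_frame)
})

test_that("gap filling restores short linear gaps and leaves long/edge gaps", {
  expect_equal(fill_gaps(c(0, 1, NA, NA, 4)), c(0, 1, 2, 3, 4))
  x3 <- c(0, 1, NA, NA, NA, 5, 6)
  expect_equal(fill_gaps(x3), x3)           # 3-frame gap exceeds the limit
  xb <- c(NA, 1, 2, 3)
  expect_equal(fill_gaps(xb), xb)           # no left anchor
  expect_warning(out <- fill_gaps(c(NA_real_, NA_real_, NA_real_)),
                 "entirely missing")
  expect_equal(out, c(NA_real_, NA_real_, NA_real_))
  # valid samples are never altered
  set.seed(4)
  x <- rnorm(50); x[c(10, 11, 25)] <- NA
  filled <- fill_gaps(x)
  expect_identical(filled[!is.na(x)], x[!is.na(x)])
  expect_false(anyNA(filled))
})

test_that("zero-phase Butterworth has unit DC gain, no phase shift, and the designed stopband", {
  expect_equal(lowpass_filter(rep(3.7, 100), fs = 25), rep(3.7, 100),
               tolerance = 1e-9)

  # 1 Hz tone at 25 Hz: passband, zero phase -> peak correlation at lag 0
  t <- seq(0, 8, by = 1 / 25)
  x <- sin(2 * pi * 1 * t)
  y <- lowpass_filter(x, fs = 25)
  lags <- -5:5
  cors <- vapply(lags, function(L) {
    i <- seq_along(t); j <- i + L
    ok <- j >= 1 & j <= length(t)
    cor(x[i[ok]], y[j[ok]])
  }, numeric(1))
  expect_equal(lags[which.max(cors)], 0)
  expect_gt(max(cors), 0.999)

  # 10 Hz tone at 100 Hz: amplitude below the two-pass Butterworth bound
  t2 <- seq(0, 4, by = 1 / 100)
  x2 <- sin(2 * pi * 10 * t2)
  y2 <- lowpass_filter(x2, fs = 100)
  mid <- t2 > 1 & t2 < 3
  gain <- max(abs(y2[mid])) / max(abs(x2[mid]))
  H2 <- 1 / (1 + (10 / 5)^(2 * 4))   # |H|^2 of the forward+backward pass
  expect_lt(gain, 0.01)
  expect_equal(gain, H2, tolerance = 0.15)

  # energy never increases for zero-mean input
  set.seed(9)
  z <- rnorm(400)
  zf <- lowpass_filter(z - mean(z), fs = 25)
  expect_lte(sum(zf^2), sum((z - mean(z))^2))

  # spans shorter than the warm-up are left unfiltered with a warning
  expect_warning(short <- lowpass_filter(sin(1:8), fs = 25), "warm-up")
  expect_equal(short, sin(1:8))
})

test_that("scaling calibration follows the reference-distance definition", {
  sc <- compute_scaling(c(100, 500), c(730, 500), 6.3)
  expect_equal(sc$reference_pixel_length, 630)
  expect_equal(sc$s, 0.01)
  sc2 <- compute_scaling(c(100, 500), c(730, 500), 12.6)
  expect_equal(sc2$s, 2 * sc$s)              # linear in distance
  expect_error(compute_scaling(c(5, 0), c(5, 100), 6.3), "zero horizontal")
})

test_that("dimensionalize scales every coordinate and preserves the rate", {
  x <- matrix(500, 3, 25); y <- matrix(250, 3, 25)
  px <- to_walking_frame(make_pose(x, y, side = "right"))
  ts <- dimensionalize(px, 0.01)
  expect_equal(unname(ts$x[1, "nose"]), 5.0)
  expect_equal(ts$sampling_rate, 25)
  ts1 <- dimensionalize(px, 1)
  expect_equal(unname(ts1$x[, "nose"]), unname(px$x[, "nose"]))
  # pelvis displacement of the synthetic bout equals the programmed length
  sim <- default_sim()
  full <- preprocess_pose(sim$pose, sim_scaling())
  disp <- diff(range(full$x[, "pelvis"]))
  expect_equal(disp, sim$spec$bout_length, tolerance = 0.01)
})

test_that("limb-swap correction repairs injected swaps and nothing else", {
  sim <- default_sim()
  clean <- to_walking_frame(sim$pose)
  out <- correct_limb_swaps(clean)
  expect_equal(nrow(attr(out, "swap_report")), 0L)   # no false alarms
  expect_equal(out$x, clean$x)

  posed <- inject_defects(sim$pose, list(swap_rate = 0.05), seed = 3)
  injected <- attr(posed, "injection_log")$swap_frames
  expect_gt(length(injected), 0)
  fixed <- correct_limb_swaps(to_walking_frame(posed))
  rep <- attr(fixed, "swap_report")
  expect_setequal(rep$frame_index[rep$action == "swapped"], injected)
  expect_equal(fixed$x, clean$x, tolerance = 1e-9)
  expect_equal(fixed$y, clean$y, tolerance = 1e-9)
  # idempotent: a second application changes nothing
  again <- correct_limb_swaps(fixed)
  expect_equal(nrow(attr(again, "swap_report")), 0L)

  # single frame: no displacement defined, unchanged
  one <- make_pose(matrix((1:25) * 10, 1), matrix((1:25) * 10, 1))
  out1 <- correct_limb_swaps(as_pixel_trajectories(one))
  expect_equal(out1$x, as_pixel_trajectories(one)$x)
})

test_that("same-leg collapsed frames are detected and the weaker leg dropped", {
  sim <- default_sim()
  px <- to_walking_frame(sim$pose)
  f <- 40L
  px$x[f, leg_keypoints("l")] <- px$x[f, leg_keypoints("r")] + 1
  px$y[f, leg_keypoints("l")] <- px$y[f, leg_keypoints("r")]
  px$conf[f, leg_keypoints("l")] <- 0.5       # weaker than the right leg
  out <- correct_limb_swaps(px)
  rep <- attr(out, "swap_report")
  expect_true(f %in% rep$frame_index[rep$action == "same_leg_dropped"])
  expect_true(all(is.na(out$x[f, leg_keypoints("l")])))
  expect_false(anyNA(out$x[f, leg_keypoints("r")]))
})

test_that("the full chain barely perturbs defect-free low-frequency content", {
  sim <- default_sim()
  ts <- preprocess_pose(sim$pose, sim_scaling())
  raw <- dimensionalize(to_walking_frame(sim$pose), sim_scaling())
  # pelvis moves at ~0.8 Hz step content: passband deviation is tiny
  for (p in c("pelvis", "trunk")) {
    dev <- max(abs(ts$x[, p] - raw$x[, p]), na.rm = TRUE)
    expect_lt(dev, 0.01 * diff(range(raw$x[, p])))
  }
})
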