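test_that("calibration recovers a planted rigid transform", {
  # identity: same frame in both cameras
  tp0 <- simulate_tpose(0, c(0, 0, 0), 0)
  cal0 <- calibrate_cameras(tp0$cam1, tp0$cam1)
  expect_equal(cal0$yaw_deg, 0)
  expect_equal(unname(cal0$translation), c(0, 0, 0))
  expect_true(cal0$valid)

  # camera 2 rotated 60 degrees about the vertical
  tp <- simulate_tpose(60, c(0, 0, 0), 0)
  cal <- calibrate_cameras(tp$cam1, tp$cam2)
  expect_lt(abs(cal$yaw_deg - 60), 1e-6)
  expect_true(cal$valid)

  # noise-free sweep over the working range
  for (theta in seq(-80, 80, by = 20)) {
    tps <- simulate_tpose(theta, c(0.3, 0, -0.4), 0)
    cals <- calibrate_cameras(tps$cam1, tps$cam2)
    expect_lt(abs(cals$yaw_deg - theta), 1e-6)
    tr <- transform_frame(tps$cam2, cals)
    expect_lt(max(abs(tr$x - tps$cam1$x)), 1e-9)
    expect_lt(max(abs(tr$z - tps$cam1$z)), 1e-9)
  }
})

test_that("calibration tolerates centimetre noise to about a degree", {
  errs <- vapply(1:20, function(i) {
    theta <- seq(-80, 80, length.out = 20)[i]
    tp <- simulate_tpose(theta, c(0.2, 0, 0.1), noise_sd = 0.01,
                         seed = 100 + i)
    calibrate_cameras(tp$cam1, tp$cam2)$yaw_deg - theta
  }, numeric(1))
  expect_lt(max(abs(errs)), 2)
})

test_that("calibration rejects wrist-span disagreement of 10 cm or more", {
  tp <- simulate_tpose(30, c(0, 0, 0), 0)
  bad <- tp$cam2
  # shorten the wrist span by 0.12 m
  w <- bad$joint == "wrist_right"
  span_dir <- c(bad$x[w] - bad$x[bad$joint == "wrist_left"],
                bad$z[w] - bad$z[bad$joint == "wrist_left"])
  shrink <- 0.12 / sqrt(sum(span_dir^2))
  bad$x[w] <- bad$x[w] - span_dir[1] * shrink
  bad$z[w] <- bad$z[w] - span_dir[2] * shrink
  expect_error(calibrate_cameras(tp$cam1, bad),
               class = "fms_calibration_error")

  # untracked wrist is a missing landmark
  bad2 <- tp$cam2
  bad2$state[bad2$joint == "wrist_left"] <- "not_tracked"
  expect_error(calibrate_cameras(tp$cam1, bad2),
               class = "fms_missing_landmark_error")
})

test_that("transform_frame follows the axis convention and inverts cleanly", {
  tp <- simulate_tpose(0, c(0, 0, 0), 0)
  # identity calibration leaves the frame unchanged
  cal_id <- fmsdetect:::new_calibration(0, c(0, 0, 0), 0)
  expect_equal(transform_frame(tp$cam1, cal_id), tp$cam1)

  # (1,0,0) under yaw 90 with zero translation -> (0,0,-1)
  cal90 <- fmsdetect:::new_calibration(90, c(0, 0, 0), 0)
  fr <- tp$cam1
  fr$x <- 1; fr$y <- 0; fr$z <- 0
  out <- transform_frame(fr, cal90)
  expect_lt(max(abs(out$x)), 1e-9)
  expect_lt(max(abs(out$z + 1)), 1e-9)

  # transform then inverse-transform returns the original positions
  cal <- fmsdetect:::new_calibration(37, c(0.4, 0.1, -0.2), 0)
  inv <- fmsdetect:::new_calibration(
    -37, -as.vector(fmsdetect:::rot_y(-37) %*% cal$translation), 0
  )
  back <- transform_frame(transform_frame(fr, cal), inv)
  expect_lt(max(abs(back$x - fr$x)), 1e-9)
  expect_lt(max(abs(back$y - fr$y)), 1e-9)
  expect_lt(max(abs(back$z - fr$z)), 1e-9)

  # an invalid calibration violates the precondition
  cal_bad <- fmsdetect:::new_calibration(0, c(0, 0, 0), 0.2)
  expect_error(transform_frame(fr, cal_bad), class = "fms_validation_error")
})

two_frame_stream <- function(xyz_by_joint, states, time = c(0, 1 / 30)) {
  n <- length(time)
  xm <- matrix(xyz_by_joint[1], n, 20)
  ym <- matrix(xyz_by_joint[2], n, 20)
  zm <- matrix(xyz_by_joint[3], n, 20)
  st <- matrix(states, n, 20)
  fmsdetect:::stream_from_matrices(time, xm, ym, zm, st, rate = 30)
}

test_that("fusion applies the per-joint branch rules", {
  cal_id <- fmsdetect:::new_calibration(0, c(0, 0, 0), 0)

  # both tracked: coordinate-wise mean
  s1 <- two_frame_stream(c(0.10, 1.00, 2.00), "tracked")
  s2 <- two_frame_stream(c(0.20, 1.00, 2.00), "tracked")
  f <- fuse_streams(s1, s2, cal_id)
  expect_equal(unique(f$x), 0.15)
  expect_equal(unique(f$y), 1.00)
  expect_equal(unique(f$provenance), "averaged")
  expect_equal(unique(f$state), "tracked")

  # tracked only in camera 1
  s2nt <- two_frame_stream(c(9, 9, 9), "not_tracked")
  s1a <- two_frame_stream(c(0.3, 0.9, 2.1), "tracked")
  f2 <- fuse_streams(s1a, s2nt, cal_id)
  expect_equal(unique(f2$x), 0.3)
  expect_equal(unique(f2$provenance), "cam1_only")

  # tracked only in camera 2
  s1nt <- two_frame_stream(c(9, 9, 9), "not_tracked")
  s2a <- two_frame_stream(c(0.4, 1.1, 2.2), "tracked")
  f3 <- fuse_streams(s1nt, s2a, cal_id)
  expect_equal(unique(f3$x), 0.4)
  expect_equal(unique(f3$provenance), "cam2_only")
  expect_equal(unique(f3$state), "tracked")

  # invalid in both: camera 1's stored position, flagged fallback
  f4 <- fuse_streams(s1nt, s2nt, cal_id)
  expect_equal(unique(f4$x), 9)
  expect_equal(unique(f4$provenance), "fallback_cam1")
  expect_equal(unique(f4$state), "not_tracked")

  # tracked beats inferred when states disagree
  s2i <- two_frame_stream(c(0.5, 1.0, 2.0), "inferred")
  f5 <- fuse_streams(s1a, s2i, cal_id)
  expect_equal(unique(f5$x), 0.3)
  expect_equal(unique(f5$provenance), "cam1_only")

  # both inferred: averaged
  s1i <- two_frame_stream(c(0.1, 1.0, 2.0), "inferred")
  s2i2 <- two_frame_stream(c(0.3, 1.0, 2.0), "inferred")
  f6 <- fuse_streams(s1i, s2i2, cal_id)
  expect_equal(unique(f6$x), 0.2)
  expect_equal(unique(f6$provenance), "averaged")
  expect_equal(unique(f6$state), "inferred")
})

test_that("self-fusion under identity calibration is the identity", {
  s <- random_stream(20, seed = 5, p_dropout = 0, p_exclusion = 0)
  cal_id <- fmsdetect:::new_calibration(0, c(0, 0, 0), 0)
  f <- fuse_streams(s, s, cal_id)
  expect_equal(f$x, s$x)
  expect_equal(f$y, s$y)
  expect_equal(f$z, s$z)
  expect_equal(unique(f$provenance), "averaged")
})

test_that("fused positions lie between the two camera views", {
  set.seed(42)
  s1 <- random_stream(15, seed = 21, p_dropout = 0, p_exclusion = 0)
  s2 <- random_stream(15, seed = 22, p_dropout = 0, p_exclusion = 0)
  cal_id <- fmsdetect:::new_calibration(0, c(0, 0, 0), 0)
  f <- fuse_streams(s1, s2, cal_id)
  expect_true(all(f$x >= pmin(s1$x, s2$x) - 1e-12 &
                  f$x <= pmax(s1$x, s2$x) + 1e-12))
})

test_that("fusion fails when the streams never overlap in time", {
  s1 <- random_stream(10, seed = 1, p_exclusion = 0)
  s2 <- random_stream(10, seed = 2, p_exclusion = 0)
  s2$time <- s2$time + 100
  cal_id <- fmsdetect:::new_calibration(0, c(0, 0, 0), 0)
  expect_error(fuse_streams(s1, s2, cal_id), class = "fms_no_overlap_error")
})

test_that("calibration serializes to JSON and back", {
  tp <- simulate_tpose(25, c(0.3, 0, 0.2), 0)
  cal <- calibrate_cameras(tp$cam1, tp$cam2)
  tf <- tempfile(fileext = ".json")
  write_calibration(cal, tf)
  back <- read_calibration(tf)
  expect_equal(back$yaw_deg, cal$yaw_deg)
  expect_equal(back$translation, cal$translation)
  expect_equal(back$valid, cal$valid)
})
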