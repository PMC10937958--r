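test_that("centroid averaging handles parts and missing data", {
  tr <- as_pose_track(data.frame(
    frame = rep(0:2, each = 3),
    bodypart = rep(c("a", "b", "c"), 3),
    x = c(0, 2, 1, 0, 2, NA, NA, NA, NA),
    y = c(0, 2, 1, 0, 2, NA, NA, NA, NA),
    likelihood = 1))
  cen <- average_position(tr)
  expect_equal(cen$x[1], 1)  # (0 + 2 + 1)/3
  expect_equal(cen$x[2], 1)  # missing part dropped: (0 + 2)/2
  expect_true(cen$interpolated[3])
  expect_equal(cen$x[3], 1)  # linear interpolation (edge rule)

  solo <- as_pose_track(data.frame(frame = 0:1, bodypart = "a",
                                   x = c(1, 2), y = c(3, 4),
                                   likelihood = 1))
  expect_equal(average_position(solo)$x, c(1, 2))
})

test_that("speed is displacement times frame rate", {
  cen <- data.frame(frame = 0:9, x = seq(0, 1.8, by = 0.2), y = 0)
  v <- compute_speed(cen, fps = 25)
  expect_equal(v[-1], rep(5, 9))  # 0.2 cm per frame at 25 fps
  expect_equal(v[1], 0)
  static <- data.frame(frame = 0:9, x = 1, y = 2)
  expect_true(all(compute_speed(static, fps = 25) == 0))

  # circular motion: speed ~ r * omega
  fps <- 100
  tt <- seq(0, 10, by = 1 / fps)
  r <- 10
  omega <- 0.5
  circ <- data.frame(frame = seq_along(tt), x = r * cos(omega * tt),
                     y = r * sin(omega * tt))
  v <- compute_speed(circ, fps = fps)
  expect_lt(abs(mean(v[-1]) / (r * omega) - 1), 0.01)
})

test_that("bout detection applies speed and duration thresholds", {
  fps <- 25
  v <- rep(3, 250)  # 10 s at 3 cm/s
  b <- detect_bouts(v, fps)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 10)
  expect_equal(b$mean_speed, 3)

  expect_equal(nrow(detect_bouts(rep(1, 250), fps)), 0)
  # 12 frames at threshold speed is below the 13-frame minimum
  v2 <- c(rep(0, 20), rep(3, 12), rep(0, 20))
  expect_equal(nrow(detect_bouts(v2, fps, bout_config(median_frames = 0))),
               0)
  v3 <- c(rep(0, 20), rep(3, 13), rep(0, 20))
  expect_equal(nrow(detect_bouts(v3, fps, bout_config(median_frames = 0))),
               1)
})

test_that("scheduled bouts are recovered with frame-level precision", {
  bs <- data.frame(start_s = c(1, 5, 9, 13, 17), end_s = c(3, 7, 11, 15, 19),
                   speed = 5)
  tr <- generate_pose_track(bs, duration_s = 21, seed = 12)
  bouts <- detect_bouts(compute_speed(average_position(tr)), fps = 25)
  expect_equal(nrow(bouts), 5)
  expect_true(all(abs(bouts$start_frame - (bs$start_s * 25 + 1)) <= 2))
  expect_true(all(abs(bouts$end_frame - bs$end_s * 25) <= 2))
})

test_that("bout statistics summarize rates and handle empty sets", {
  bouts <- data.frame(start_frame = 1:6, end_frame = 2:7,
                      duration_s = 1, mean_speed = 4, distance_cm = 4)
  st <- bout_statistics(bouts, window_s = 20 * 60)
  expect_equal(st$bout_rate_per_min, 0.3)
  empty <- detect_bouts(rep(0, 100), 25)
  st0 <- bout_statistics(empty, 60)
  expect_equal(st0$bout_rate_per_min, 0)
  expect_true(is.na(st0$mean_speed))
  expect_error(bout_statistics(bouts, 0), "> 0")
})

test_that("speed and distance are invariant to rigid motions", {
  set.seed(13)
  cen <- data.frame(frame = 1:100, x = cumsum(rnorm(100, 0.2)),
                    y = cumsum(rnorm(100, 0.1)))
  th <- 0.7
  rot <- data.frame(frame = cen$frame,
                    x = cos(th) * cen$x - sin(th) * cen$y + 12,
                    y = sin(th) * cen$x + cos(th) * cen$y - 5)
  expect_equal(compute_speed(cen, 25), compute_speed(rot, 25),
               tolerance = 1e-12)
})

test_that("cumulative turning integrates heading changes with sign", {
  # straight path
  straight <- data.frame(frame = 1:100, x = seq(0, 20, length.out = 100),
                         y = 0)
  expect_lt(abs(cumulative_turning(straight, fps = 25)), 1)

  # full counterclockwise circle = +360, clockwise = -360
  fps <- 25
  tt <- seq(0, 2 * pi, length.out = 500)
  ccw <- data.frame(frame = seq_along(tt), x = 10 * cos(tt),
                    y = 10 * sin(tt))
  expect_lt(abs(cumulative_turning(ccw, fps = fps) - 360), 5)
  cw <- data.frame(frame = seq_along(tt), x = 10 * cos(-tt),
                   y = 10 * sin(-tt))
  expect_lt(abs(cumulative_turning(cw, fps = fps) + 360), 5)

  # heading undefined when nearly static
  still <- data.frame(frame = 1:100, x = rep(0, 100), y = rep(0, 100))
  expect_error(cumulative_turning(still, fps = 25), "undefined")
})

test_that("pose-track CSV dialects round-trip through the reader", {
  tr <- generate_pose_track(data.frame(start_s = 1, end_s = 3, speed = 5),
                            duration_s = 5, seed = 14)
  dir <- withr::local_tempdir()
  # long format
  longp <- file.path(dir, "long.csv")
  write.csv(as.data.frame(tr), longp, row.names = FALSE)
  back <- read_pose_track(longp)
  tr_sorted <- as.data.frame(tr)[order(tr$frame, tr$bodypart), ]
  expect_equal(back$x, tr_sorted$x, tolerance = 1e-6)

  # 3-row header dialect
  widep <- file.path(dir, "wide.csv")
  parts <- unique(tr$bodypart)
  hdr1 <- paste(c("scorer", rep("model", 3 * length(parts))), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(parts, each = 3)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
                collapse = ",")
  frames <- sort(unique(tr$frame))
  body <- vapply(frames, function(fr) {
    vals <- unlist(lapply(parts, function(p) {
      r <- tr[tr$frame == fr & tr$bodypart == p, ]
      c(r$x, r$y, r$likelihood)
    }))
    paste(c(fr, format(vals, digits = 10)), collapse = ",")
  }, character(1))
  writeLines(c(hdr1, hdr2, hdr3, body), widep)
  wide <- read_pose_track(widep)
  cen_a <- average_position(wide)
  cen_b <- average_position(back)
  expect_equal(cen_a$x, cen_b$x, tolerance = 1e-6)
})
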