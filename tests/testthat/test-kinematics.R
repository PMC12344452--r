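# Body frame, tail angle, angular velocity, polar histogram, features.

test_that("body frame axes follow the image-coordinate convention", {
  bf <- body_frame(c(0, 0), c(0, 10))
  expect_equal(bf$axis_b, c(0, 1))
  expect_equal(bf$axis_r, c(-1, 0))
  expect_true(bf$valid)

  bfm <- body_frame(c(0, 0), c(0, 10), handedness = "mirrored")
  expect_equal(bfm$axis_r, c(1, 0))

  expect_false(body_frame(c(5, 5), c(5, 5))$valid)
  expect_false(body_frame(c(0, 0), c(0.5, 0))$valid)  # below eps = 1 px
})

test_that("body frame axes are orthonormal for random geometry", {
  set.seed(41)
  for (i in 1:1000) {
    S <- runif(2, -500, 500); B <- S + rnorm(2, 0, 50)
    bf <- body_frame(S, B)
    if (!bf$valid) next
    expect_lt(abs(sum(bf$axis_b * bf$axis_r)), 1e-12)
    expect_lt(abs(sqrt(sum(bf$axis_b^2)) - 1), 1e-12)
    expect_lt(abs(sqrt(sum(bf$axis_r^2)) - 1), 1e-12)
  }
})

test_that("tail angle matches hand-checked geometry", {
  bf <- body_frame(c(0, 0), c(0, 10))
  # straight behind: collinear with the body axis
  expect_equal(tail_angle(c(0, 20), bf), 0)
  # (-5, 10): displaced along axis_r = (-1, 0), the dog's right
  expect_equal(tail_angle(c(-5, 10), bf), 90)
  expect_equal(tail_angle(c(5, 10), bf), -90)
  expect_true(is.na(tail_angle(c(NA, 10), bf)))
})

test_that("extracted angle equals the generating angle on constructed frames", {
  set.seed(42)
  for (i in 1:50) {
    theta <- runif(20, -179, 179)
    fr <- frames_from_theta(theta, S = runif(2, -200, 200),
                            B = runif(2, 300, 500))
    ts <- tail_angle_series(fr)
    expect_lt(max(abs(ts$theta - theta)), 1e-9)
  }
})

test_that("tail angle is invariant under rigid transforms", {
  set.seed(43)
  theta <- runif(30, -170, 170)
  fr <- frames_from_theta(theta)
  base <- tail_angle_series(fr)$theta
  for (i in 1:50) {
    fr2 <- apply_rigid(fr, angle = runif(1, 0, 2 * pi),
                       shift = runif(2, -1000, 1000),
                       scale = runif(1, 0.2, 5))
    expect_lt(max(abs(tail_angle_series(fr2)$theta - base)), 1e-6)
  }
})

test_that("mirroring flips the angle sign and swaps left/right features", {
  theta <- c(-20, -5, 10, 15, 30, -40)
  fr <- frames_from_theta(theta)
  fm <- apply_mirror(fr)
  expect_equal(tail_angle_series(fm)$theta, -theta, tolerance = 1e-9)

  f1 <- extract_features(trajectory_segment(fr))
  f2 <- extract_features(trajectory_segment(fm))
  expect_equal(f2$mean_angle, -f1$mean_angle)
  expect_equal(f2$amp_positive, f1$amp_negative)
  expect_equal(f2$amp_negative, f1$amp_positive)
  expect_equal(f2$sum_positive, f1$sum_negative)
  expect_equal(f2$sum_negative, f1$sum_positive)
  expect_equal(f2$mean_abs_velocity, f1$mean_abs_velocity)
})

test_that("angular velocity handles rate modes and the 180-degree cut", {
  t <- (0:2) / 60
  expect_equal(angular_velocity(c(10, 20, 30), t), c(600, 600))
  expect_equal(angular_velocity(c(10, 20, 30), t, mode = "per_frame"),
               c(10, 10))
  expect_equal(angular_velocity(c(5, 5, 5), t), c(0, 0))
  # wrap: 179 -> -179 is a +2 degree step, not -358
  expect_equal(angular_velocity(c(179, -179), t[1:2], mode = "per_frame"), 2)
  expect_equal(angular_velocity(c(-179, 179), t[1:2], mode = "per_frame"), -2)
  expect_error(angular_velocity(c(1, 2), c(0, 0)), "increasing")
})

test_that("angular velocity masks pairs spanning masked frames", {
  th <- c(10, NA, 30, 40)
  w <- angular_velocity(th, (0:3) / 60)
  expect_true(is.na(w[1]) && is.na(w[2]))
  expect_equal(w[3], 600)
})

test_that("polar histogram bins, clips and conserves counts", {
  ph <- polar_histogram(rep(0, 7), n_sectors = 18)
  expect_equal(sum(ph$counts), 7)
  expect_equal(ph$counts[10], 7)  # sector [0, 10)

  # uniform grid over the open semicircle: equal counts within 1
  th <- seq(-89.99, 89.99, length.out = 1800)
  ph2 <- polar_histogram(th, 18)
  expect_lte(diff(range(ph2$counts)), 1)
  expect_equal(ph2$n_frames, 1800)

  # clipping into terminal sectors
  ph3 <- polar_histogram(c(120, -150, 45), 18)
  expect_equal(ph3$counts[18], 1)
  expect_equal(ph3$counts[1], 1)
  expect_error(polar_histogram(1:3, 1), "n_sectors")
})

test_that("feature extraction matches hand computations", {
  f <- extract_features(segment_from_theta(rep(10, 6)))
  expect_equal(f$mean_angle, 10)
  expect_equal(f$amp_positive, 10)
  expect_equal(f$amp_negative, 0)
  expect_equal(f$mean_abs_velocity, 0)
  expect_equal(f$sum_positive, 1)
  expect_equal(f$sum_negative, 0)

  # 5-frame toy at 60 fps
  f2 <- extract_features(segment_from_theta(c(-20, -5, 0, 15, 30)))
  expect_equal(f2$mean_angle, 4)
  expect_equal(f2$amp_positive, 30)
  expect_equal(f2$amp_negative, 20)
  expect_equal(f2$sum_positive, 0.4)
  expect_equal(f2$sum_negative, 0.4)
  expect_equal(f2$mean_abs_velocity, 60 * (15 + 5 + 15 + 15) / 4)
})

test_that("occupancy partition sums to one exactly", {
  set.seed(44)
  for (i in 1:200) {
    n <- sample(3:400, 1)
    theta <- sample(c(-1, 0, 1), n, replace = TRUE) * runif(n, 0, 90)
    f <- extract_features(segment_from_theta(theta))
    expect_identical(f$sum_positive + f$sum_negative + f$zero_fraction, 1)
  }
})

test_that("confidence filter masks and interpolates correctly", {
  # no masking at full confidence
  expect_equal(confidence_filter(c(1, 2, 3), conf = c(1, 1, 1)), c(1, 2, 3))
  # single low-confidence frame: linear midpoint
  expect_equal(confidence_filter(c(10, 99, 20), conf = c(1, 0.1, 1)),
               c(10, 15, 20))
  # long runs stay masked
  out <- confidence_filter(c(1, NA, NA, NA, 5), max_gap = 2)
  expect_true(all(is.na(out[2:4])))
  # random masks against a piecewise-linear oracle
  set.seed(45)
  for (i in 1:50) {
    n <- 40
    th <- cumsum(rnorm(n))
    conf <- ifelse(runif(n) < 0.2, 0.1, 1)
    conf[c(1, n)] <- 1
    got <- confidence_filter(th, conf, threshold = 0.5, max_gap = 1000)
    keep <- conf >= 0.5
    oracle <- approx(which(keep), th[keep], xout = seq_len(n))$y
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("feature extraction fails cleanly on too few valid frames", {
  fr <- frames_from_theta(c(0, 0, 0), conf = 0.1)
  expect_error(extract_features(trajectory_segment(fr)), "too few")
})
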