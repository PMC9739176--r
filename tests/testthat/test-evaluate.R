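samples_fixture <- function(x, y, tx, ty, valid = TRUE) {
  tibble::tibble(x_mm = x, y_mm = y, truth_x_mm = tx, truth_y_mm = ty,
                 valid = valid)
}

test_that("tracking error is the mean displacement vector", {
  s0 <- samples_fixture(rep(3, 5), rep(90, 5), 3, 90)
  e0 <- tracking_error(s0)
  expect_equal(c(e0$e_x_mm, e0$e_y_mm, e0$e_mag_mm), c(0, 0, 0))

  s1 <- samples_fixture(rep(4, 6), rep(88, 6), 3, 90)
  e1 <- tracking_error(s1)
  expect_equal(c(e1$e_x_mm, e1$e_y_mm), c(1, -2))
  expect_equal(e1$e_mag_mm, sqrt(5))

  # random data against a direct oracle
  set.seed(23)
  s2 <- samples_fixture(rnorm(18, 10), rnorm(18, 100), 10, 100)
  e2 <- tracking_error(s2)
  expect_equal(e2$e_x_mm, mean(s2$x_mm) - 10, tolerance = 1e-12)
  expect_equal(e2$e_y_mm, mean(s2$y_mm) - 100, tolerance = 1e-12)
  expect_equal(e2$e_mag_frame_mean_mm,
               mean(sqrt((s2$x_mm - 10)^2 + (s2$y_mm - 100)^2)),
               tolerance = 1e-12)

  # invalid rows are excluded and counted
  s3 <- samples_fixture(c(1, 100), c(90, 90), 1, 90, valid = c(TRUE, FALSE))
  e3 <- tracking_error(s3)
  expect_equal(e3$e_x_mm, 0)
  expect_identical(e3$n_valid, 2L - 1L)
})

test_that("repeatability is the per-axis sample standard deviation", {
  s0 <- samples_fixture(rep(1, 4), rep(2, 4), 1, 2)
  r0 <- repeatability(s0)
  expect_equal(c(r0$rep_x_mm, r0$rep_y_mm, r0$rep_mag_mm), c(0, 0, 0))

  n <- 18
  s1 <- samples_fixture(rep(c(1, -1), n / 2), rep(0, n), 0, 0)
  r1 <- repeatability(s1)
  expect_equal(r1$rep_x_mm, sqrt(n / (n - 1)))

  set.seed(24)
  s2 <- samples_fixture(rnorm(18), rnorm(18), 0, 0)
  r2 <- repeatability(s2)
  expect_equal(r2$rep_x_mm, sd(s2$x_mm))
  expect_equal(r2$rep_mag_mm, sqrt(var(s2$x_mm) + var(s2$y_mm)))
})

test_that("repeat averaging reports mean and std-error across repeats", {
  m1 <- tibble::tibble(position_id = 1:2, e_mag_mm = c(0, 1))
  m2 <- tibble::tibble(position_id = 1:2, e_mag_mm = c(0, 0))
  same <- repeat_average(list(m1, m1), cols = "e_mag_mm")
  expect_equal(same$e_mag_mm_se, c(0, 0))

  two <- repeat_average(list(m1, m2), cols = "e_mag_mm")
  expect_equal(two$e_mag_mm_mean[2], 0.5)
  expect_equal(two$e_mag_mm_se[2], sd(c(1, 0)) / sqrt(2))

  set.seed(25)
  reps <- lapply(1:5, function(k) {
    tibble::tibble(position_id = 1:3, e_mag_mm = runif(3))
  })
  five <- repeat_average(reps, cols = "e_mag_mm")
  vals <- sapply(reps, function(m) m$e_mag_mm[2])
  expect_equal(five$e_mag_mm_mean[2], mean(vals))
  expect_equal(five$e_mag_mm_se[2], sd(vals) / sqrt(5))
})

test_that("spatial summary reduces per-location metrics", {
  m <- tibble::tibble(e_mag_mm = c(1, 1, 1), rep_mag_mm = c(0.2, 0.2, 0.2))
  s <- spatial_summary(m)
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$mean, c(1, 0.2))

  m2 <- tibble::tibble(e_mag_mm = c(0.1, 0.5, 0.9))
  s2 <- spatial_summary(m2, cols = "e_mag_mm", p = 50)
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$sd, sd(c(0.1, 0.5, 0.9)))
  expect_equal(s2$p50, 0.5)

  # percentile by linear interpolation on a uniform ladder
  m3 <- tibble::tibble(e_mag_mm = seq(0, 1, length.out = 101))
  s3 <- spatial_summary(m3, cols = "e_mag_mm", p = 95)
  expect_equal(s3$p95, 0.95, tolerance = 1e-9)
})

test_that("label offsets are removed along the shaft direction", {
  labs <- tibble::tibble(x_mm = c(10, 20), y_mm = c(100, 110))
  expect_equal(label_offset_correction(labs, 0, 55), labs)

  h <- label_offset_correction(labs, 3.5, 0)
  expect_equal(h$x_mm, labs$x_mm - 3.5)
  expect_equal(h$y_mm, labs$y_mm)

  a <- label_offset_correction(labs, 3.5, 55)
  expect_equal(a$x_mm, labs$x_mm - 3.5 * cos(55 * pi / 180))
  expect_equal(a$y_mm, labs$y_mm - 3.5 * sin(55 * pi / 180))
})

test_that("the uncertainty correlation is a Pearson coefficient", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(uncertainty_correlation(x, 2 * x), 1)
  expect_equal(uncertainty_correlation(x, 10 - 3 * x), -1)

  set.seed(26)
  a <- runif(50)
  b <- a + rnorm(50, sd = 0.3)
  textbook <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(uncertainty_correlation(a, b), textbook, tolerance = 1e-12)
})

kalman_track <- function(x, y, sx = 0.5, sy = 0.5, valid = TRUE) {
  n <- length(x)
  tibble::tibble(x_mm = x, y_mm = y, sigma_x_mm = sx, sigma_y_mm = sy,
                 cov_xy_mm2 = 0, valid = rep_len(valid, n))
}

test_that("Kalman smoothing converges on stationary and constant-velocity
           tracks", {
  st <- kalman_track(rep(10, 40), rep(100, 40))
  sm <- kalman_smooth(st)
  expect_lt(max(abs(sm$x_smooth_mm[20:40] - 10)), 1e-6)
  expect_lt(max(abs(sm$y_smooth_mm[20:40] - 100)), 1e-6)

  dt <- 1 / 18
  tt <- (0:119) * dt
  cv <- kalman_track(5 + 20 * tt, 100 - 10 * tt)
  smv <- kalman_smooth(cv, model = "constant_velocity")
  tail_idx <- 100:120
  expect_lt(max(abs(smv$x_smooth_mm[tail_idx] - cv$x_mm[tail_idx])), 1e-6)
  expect_lt(max(abs(smv$y_smooth_mm[tail_idx] - cv$y_mm[tail_idx])), 1e-6)

  smv2 <- kalman_smooth(cv, model = "constant_acceleration")
  expect_lt(max(abs(smv2$x_smooth_mm[tail_idx] - cv$x_mm[tail_idx])), 1e-4)
})

test_that("Kalman smoothing reduces jitter and rides through dropouts", {
  set.seed(27)
  n <- 200
  jit <- kalman_track(10 + rnorm(n, sd = 0.5), 100 + rnorm(n, sd = 0.5))
  sm <- kalman_smooth(jit)
  core <- 50:n
  expect_lt(var(sm$x_smooth_mm[core]), var(jit$x_mm[core]))
  expect_lt(var(sm$y_smooth_mm[core]), var(jit$y_mm[core]))
  # roughly threefold RMS reduction at the default settings
  expect_lt(sd(sm$x_smooth_mm[core] - 10), 0.5 * sd(jit$x_mm[core] - 10))

  drop <- kalman_track(rep(10, 30), rep(100, 30),
                       valid = c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 15)))
  smd <- kalman_smooth(drop)
  expect_true(all(is.finite(smd$x_smooth_mm[11:15])))  # predicted through
  expect_lt(max(abs(smd$x_smooth_mm[25:30] - 10)), 1e-6)
})

test_that("elevation analysis summarises displacement, repeatability and
           SNR by z", {
  sim <- generate_elevation_sweep(
    geometry = small_geometry(), depth_mm = 120, z_range = c(-10, 10),
    step = 5, focal_depth_mm = 120, n_frames = 4, snr_db = 55, seed = 6
  )
  curves <- elevation_analysis(sim)
  expect_identical(nrow(curves), 5L)
  i0 <- which(curves$z_mm == 0)
  expect_lt(abs(curves$disp_x_mm[i0]), 0.3)
  expect_lt(abs(curves$disp_y_mm[i0]), 0.3)
  # SNR falls moving out of plane, roughly symmetrically
  expect_true(all(curves$snr_db[i0] >= curves$snr_db[-i0]))
  expect_equal(curves$snr_db[curves$z_mm == 10],
               curves$snr_db[curves$z_mm == -10], tolerance = 0.1)
})

test_that("angle analysis shows the raw rise and processed flatness", {
  sim <- generate_angle_sweep(
    geometry = small_geometry(), depth_mm = 150,
    angles = c(0, 20, 40, 60), n_frames = 2, snr_db = 70, seed = 7
  )
  amp <- angle_analysis(sim)
  expect_identical(nrow(amp), 4L)
  expect_gt(amp$raw_amp[amp$angle_deg == 40] / amp$raw_amp[amp$angle_deg == 0],
            1.5)
  rel <- amp$proc_amp / amp$proc_amp[1]
  expect_true(all(abs(rel - 1) < 0.10))
  expect_true(all(amp$raw_amp_sd >= 0))
})
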