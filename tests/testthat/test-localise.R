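make_ce <- function(en, th) {
  geom_dummy <- NULL
  f <- foh_frame(matrix(1, 2, length(en)), FS, th)
  ce <- column_energies(f, threshold_db = -6)
  ce$en <- en
  ce$n_prime <- sum(en > 0)
  ce$theta_deg <- th
  ce
}

test_that("column energies apply the -6 dB threshold", {
  geom <- small_geometry(n_lines = 3)
  m <- matrix(0, 16, 3)
  m[5, 2] <- 1
  ce <- column_energies(foh_frame(m, FS, scan_line_angles(geom)))
  expect_equal(ce$en > 0, c(FALSE, TRUE, FALSE))
  expect_identical(ce$n_prime, 1L)

  # energies (1.0, 0.20): 0.20 falls below 10^(-0.6) = 0.251 of the max
  m2 <- matrix(0, 16, 3)
  m2[5, 1] <- 1
  m2[5, 2] <- sqrt(0.20)
  m2[5, 3] <- sqrt(0.26)
  ce2 <- column_energies(foh_frame(m2, FS, scan_line_angles(geom)))
  expect_equal(ce2$en > 0, c(TRUE, FALSE, TRUE))

  # uniform energies all survive
  ce3 <- column_energies(foh_frame(matrix(1, 8, 3), FS,
                                   scan_line_angles(geom)))
  expect_identical(ce3$n_prime, 3L)

  cez <- column_energies(foh_frame(matrix(0, 8, 3), FS,
                                   scan_line_angles(geom)))
  expect_true(cez$degenerate)
})

test_that("the weighted mean angle is the energy centre of mass", {
  expect_equal(weighted_mean_angle(make_ce(c(0, 1, 0), c(-1, 0, 1))), 0)
  expect_equal(weighted_mean_angle(make_ce(c(1, 1), c(10, 20))), 15)
  expect_equal(weighted_mean_angle(make_ce(c(1, 3), c(0, 4))), 3)
  expect_error(weighted_mean_angle(make_ce(c(0, 0), c(0, 1))), "no signal")
})

test_that("the weighted angular spread behaves as an energy width", {
  ce1 <- make_ce(c(0, 5, 0), c(-1, 0, 1))
  expect_equal(as.numeric(weighted_angle_spread(ce1, 0)), 0)

  ce2 <- make_ce(c(2, 2), c(-1, 1))
  expect_equal(weighted_angle_spread(ce2, 0), sqrt(2))
  # the literal printed form for the same case
  expect_equal(weighted_angle_spread(ce2, 0, form = "printed"), sqrt(0.5))

  # invariant under global energy scaling
  ce3 <- make_ce(c(1, 2, 3), c(-2, 0, 2))
  tb <- weighted_mean_angle(ce3)
  ce3k <- make_ce(7.3 * c(1, 2, 3), c(-2, 0, 2))
  expect_equal(weighted_angle_spread(ce3, tb),
               weighted_angle_spread(ce3k, tb))
})

test_that("time of arrival is exact for a rectangular envelope", {
  fs <- FS
  j0 <- 101
  m <- 80
  x <- numeric(1000)
  x[j0:(j0 + m - 1)] <- 0.7
  toa <- time_of_arrival(x, fs)
  expect_equal(toa$t_start, (j0 - 1) / fs, tolerance = 1e-15)
  expect_equal(1.25 * toa$delta_t, m / fs, tolerance = 1e-15)

  # shifting the pulse shifts the start exactly
  sh <- 57
  x2 <- c(numeric(sh), x)[1:1000]
  toa2 <- time_of_arrival(x2, fs)
  expect_equal(toa2$t_start - toa$t_start, sh / fs, tolerance = 1e-15)

  expect_error(time_of_arrival(numeric(10), fs), "no signal")
})

test_that("time of arrival matches an oversampled oracle for a Gaussian
           envelope", {
  fs <- FS
  t0 <- 40e-6
  sigma <- 1.5e-6
  env <- function(t) exp(-(t - t0)^2 / (2 * sigma^2))
  x <- env((0:999) / fs)
  got <- time_of_arrival(x, fs)

  # oracle: same left-edge cumulative-energy convention on a 100x finer grid
  fs_hi <- fs * 100
  xh <- env((0:99999) / fs_hi)
  eh <- cumsum(xh^2) / fs_hi
  total <- eh[length(eh)]
  t_at <- function(q) approx(c(0, eh), (0:length(eh)) / fs_hi,
                             xout = q * total, ties = "ordered")$y
  dt_o <- t_at(0.9) - t_at(0.1)
  start_o <- t_at(0.1) - 0.125 * dt_o
  expect_lt(abs(got$t_start - start_o), 1 / fs)
  expect_lt(abs(got$delta_t - dt_o), 1 / fs)
})

test_that("radial position implements r = c t + rho and sigma_r = 1.25 c dt", {
  geom <- probe_geometry(rho_mm = 40)
  rp <- radial_position(2e-5, 0, geom, delay_s = 2e-5)
  expect_equal(rp$r_mm, 40)

  rp2 <- radial_position(64.935e-6 + 2e-5, 1e-6, geom, delay_s = 2e-5)
  expect_equal(rp2$r_mm, 140.0, tolerance = 1e-3)
  expect_equal(rp2$sigma_r_mm, 1.925)

  expect_error(radial_position(1e-5, 0, geom, delay_s = 2e-5), "pre-transmit")
})

test_that("localise_frame recovers a clean on-axis pose and flags noise", {
  geom <- small_geometry()
  pm <- pulse_model()
  tmpl <- default_template(pm)
  spacing <- 55 / (geom$n_lines - 1)
  c_per_sample <- 1540 * 1000 / FS  # mm travelled per sample

  sc <- simulation_scene(0, 68 + 100, snr_db = Inf)
  fr <- generate_frame(sc, geom, pm, FS)
  est <- localise_frame(fr, tmpl, geom)
  expect_true(est$valid)
  expect_equal(est$method, "centre_of_mass")
  expect_lt(abs(est$theta_deg), spacing / 2)
  expect_lt(abs(est$r_mm - 168), 1.5 * c_per_sample)

  # pure noise with a matched noise level is gated out
  nz <- noise_frame(geom, sd = 0.02, seed = 31)
  nl <- noise_level(preprocess_frame(noise_frame(geom, sd = 0.02, seed = 32),
                                     tmpl))
  est_nz <- localise_frame(nz, tmpl, geom, noise = nl)
  expect_false(est_nz$valid)

  # symmetric two-line energy: the angle lands exactly midway
  two <- template_frame(tmpl, geom,
                        amplitudes = replace(numeric(64), 30:31, 1),
                        at = 500)
  est2 <- localise_frame(two, tmpl, geom)
  angles <- scan_line_angles(geom)
  expect_equal(est2$theta_deg, mean(angles[30:31]), tolerance = 1e-9)
  expect_equal(est2$method, "centre_of_mass")

  # the angle is invariant to global amplitude scaling
  two_big <- two
  two_big$samples <- two$samples * 37
  expect_equal(localise_frame(two_big, tmpl, geom)$theta_deg,
               est2$theta_deg, tolerance = 1e-12)
})

test_that("localisation round-trips random clean poses within tolerance", {
  geom <- small_geometry()
  pm <- pulse_model()
  tmpl <- default_template(pm)
  offset <- fohtrack:::template_toa_offset(tmpl)
  spacing <- 55 / (geom$n_lines - 1)
  c_per_sample <- 1540 * 1000 / FS
  set.seed(17)
  for (i in 1:25) {
    th <- runif(1, -24, 24)
    r <- runif(1, 108, 260)
    xy <- polar_to_cartesian(r, th)
    fr <- generate_frame(simulation_scene(xy$x, xy$y, snr_db = Inf),
                         geom, pm, FS)
    est <- localise_frame(fr, tmpl, geom, toa_offset_s = offset)
    expect_true(est$valid)
    expect_lt(abs(est$r_mm - r), 1.5 * c_per_sample)
    expect_lt(abs(est$theta_deg - th), spacing / 2)
  }
})

test_that("repeatability degrades as SNR falls and tracks the estimated
           spread", {
  geom <- small_geometry()
  pm <- pulse_model()
  tmpl <- default_template(pm)
  offset <- fohtrack:::template_toa_offset(tmpl)
  levels <- c(20, 40, 60)
  reps <- sigmas <- numeric(length(levels))
  for (L in seq_along(levels)) {
    ests <- lapply(1:30, function(k) {
      fr <- generate_frame(
        simulation_scene(15, 68 + 120, snr_db = levels[L]),
        geom, pm, FS, seed = 1000 * L + k
      )
      localise_frame(fr, tmpl, geom, toa_offset_s = offset)
    })
    th <- vapply(ests, function(e) e$theta_deg, numeric(1))
    st <- vapply(ests, function(e) e$sigma_theta_deg, numeric(1))
    reps[L] <- sd(th)
    sigmas[L] <- mean(st)
  }
  expect_true(all(diff(reps) < 0))   # repeatability improves with SNR
  expect_gt(cor(sigmas, reps), 0.5)  # estimated spread tracks it
})
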