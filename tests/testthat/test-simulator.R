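test_that("synthesised pulses have the modelled spectrum", {
  pm <- pulse_model()
  w0 <- synthesize_pulse(pm, FS, needle_angle = 0)
  expect_equal(mean(w0), 0, tolerance = 1e-12)
  expect_equal(max(w0), 1, tolerance = 2e-3)  # unit peak of the f0 component

  # spectral peak at f0, and < 1% of energy outside the main band
  n <- 4096
  spec <- Mod(fft(c(w0, numeric(n - length(w0)))))^2
  freqs <- (seq_len(n) - 1) / n * FS
  half <- freqs <= FS / 2
  expect_equal(freqs[half][which.max(spec[half])], 2e6, tolerance = 0.05)
  band <- freqs >= 2e6 * (1 - 0.6) & freqs <= 2e6 * (1 + 0.6)
  out_frac <- sum(spec[half & !band]) / sum(spec[half])
  expect_lt(out_frac, 0.01)

  expect_error(synthesize_pulse(pm, 3e6), "aliasing")
})

test_that("the low-frequency component raises the raw peak by ~67% at 40 deg", {
  pm <- pulse_model()
  w0 <- synthesize_pulse(pm, FS, 0)
  w40 <- synthesize_pulse(pm, FS, 40)
  ratio <- max(abs(w40)) / max(abs(w0))
  expect_gt(ratio, 1.55)
  expect_lt(ratio, 1.70)
  # flat beyond 40 degrees
  w60 <- synthesize_pulse(pm, FS, 60)
  expect_equal(max(abs(w60)), max(abs(w40)), tolerance = 1e-9)
})

test_that("clean frames place the pulse on the right line at the right time", {
  geom <- small_geometry()
  pm <- pulse_model()
  angles <- scan_line_angles(geom)
  k <- 40L
  xy <- polar_to_cartesian(140, angles[k])
  sc <- simulation_scene(xy$x, xy$y, snr_db = Inf)
  fr <- generate_frame(sc, geom, pm, FS)
  peak <- arrayInd(which.max(abs(fr$samples)), dim(fr$samples))
  expect_identical(peak[1, 2], k)
  wave <- synthesize_pulse(pm, FS, 0)
  expected <- round((sc$trigger_to_transmit_delay_s +
                       (140 - 68) / 1000 / 1540) * FS) + attr(wave, "centre")
  expect_lte(abs(peak[1, 1] - expected), 1)
})

test_that("frames are deterministic in (scene, seed) and noise scales to SNR", {
  geom <- small_geometry()
  pm <- pulse_model()
  sc_inf <- simulation_scene(20, 150, snr_db = Inf)
  f1 <- generate_frame(sc_inf, geom, pm, FS, seed = 5)
  f2 <- generate_frame(sc_inf, geom, pm, FS, seed = 5)
  expect_identical(f1$samples, f2$samples)

  sc60 <- simulation_scene(20, 150, snr_db = 60)
  f60 <- generate_frame(sc60, geom, pm, FS, seed = 5)
  # the clean part is unchanged: the residual is pure noise at the set RMS
  resid <- f60$samples - f1$samples
  target_rms <- max(abs(f1$samples)) / 10^(60 / 20)
  expect_equal(sqrt(mean(resid^2)), target_rms, tolerance = 0.01)

  # measured peak/RMS over repeated 40 dB frames stays within +/- 1 dB
  sc40 <- simulation_scene(20, 150, snr_db = 40)
  snrs <- vapply(1:100, function(s) {
    f <- generate_frame(sc40, geom, pm, FS, seed = s, window = 1280)
    nz <- f$samples - generate_frame(sc_inf, geom, pm, FS, window = 1280)$samples
    20 * log10(max(abs(f1$samples)) / sqrt(mean(nz^2)))
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 40), 1)
})

test_that("the default grid reproduces the 356-location layout", {
  sim <- generate_grid_dataset(seed = 1)
  expect_identical(nrow(sim$truth), 356L)
  expect_identical(max(sim$scenes$frame), 18L)
  expect_identical(nrow(sim$scenes), 356L * 18L)
  # all positions inside the fan, right-hand side, 40-140 mm deep
  pol <- cartesian_to_polar(sim$truth$x_mm, sim$truth$y_mm)
  expect_true(all(abs(pol$theta_deg) <= 27.5 + 1e-9))
  expect_true(all(sim$truth$x_mm >= 0))
  expect_true(all(sim$truth$y_mm >= 68 + 40 & sim$truth$y_mm <= 68 + 140))

  # a coarser lattice matches an independent brute-force enumeration
  sim10 <- generate_grid_dataset(
    grid_spec = list(depth_range = c(40, 140), spacing = 10, side = "right"),
    n_frames_per_pos = 1, seed = 1
  )
  count <- 0
  for (d in seq(40, 140, 10)) {
    y <- 68 + d
    for (x in seq(0, 200, 10)) {
      if (abs(atan2(x, y) * 180 / pi) <= 27.5) count <- count + 1
    }
  }
  expect_identical(nrow(sim10$truth), as.integer(count))
})

test_that("elevation sweep covers 73 positions with a symmetric beam", {
  sim <- generate_elevation_sweep(geometry = small_geometry(), depth_mm = 120,
                                  seed = 2)
  expect_identical(nrow(sim$truth), 73L)
  expect_equal(range(sim$truth$z_mm), c(-36, 36))

  # clean amplitude maximal in plane and non-increasing in |z|
  geom <- small_geometry()
  pm <- pulse_model()
  zs <- c(0, 5, 12, 25)
  peaks <- vapply(zs, function(z) {
    sc <- simulation_scene(0, 68 + 120, z_mm = z, snr_db = Inf,
                           focal_depth_mm = 140)
    max(abs(generate_frame(sc, geom, pm, FS)$samples))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("angle sweep varies only the needle angle", {
  sim <- generate_angle_sweep(geometry = small_geometry(), seed = 3)
  expect_identical(nrow(sim$truth), 13L)
  expect_equal(sim$truth$angle_deg, seq(0, 60, 5))
  expect_true(all(sim$truth$x_mm == 0))

  # the 0-degree scene frame equals a plain generate_frame with the same seed
  geom <- small_geometry()
  pm <- pulse_model()
  i0 <- which(sim$scenes$position_id == 1 & sim$scenes$frame == 1)
  f_sweep <- sim_frame(sim, i0)
  sc <- simulation_scene(0, 68 + 150, needle_angle_deg = 0,
                         snr_db = sim$snr_db)
  f_plain <- generate_frame(sc, geom, pm, sim$sample_rate, sim$window,
                            seed = sim$scenes$seed[i0],
                            noise_rms = sim$noise_rms)
  expect_identical(f_sweep$samples, f_plain$samples)

  # raw amplitude rises with angle through the low-frequency ramp
  i40 <- which(sim$scenes$position_id == 9 & sim$scenes$frame == 1)  # 40 deg
  expect_gt(max(abs(sim_frame(sim, i40)$samples)),
            1.4 * max(abs(f_sweep$samples)))
})

test_that("the -6 dB angular support of a clean frame is centred on the tip", {
  geom <- small_geometry()
  pm <- pulse_model()
  angles <- scan_line_angles(geom)
  spacing <- angles[2] - angles[1]
  set.seed(21)
  for (i in 1:5) {
    th <- runif(1, -20, 20)
    xy <- polar_to_cartesian(runif(1, 110, 240), th)
    fr <- generate_frame(simulation_scene(xy$x, xy$y, snr_db = Inf),
                         geom, pm, FS)
    en <- colSums(fr$samples^2)
    keep <- which(en >= max(en) * 10^(-6 / 10))
    centre <- mean(angles[range(keep)])
    expect_lt(abs(centre - th), spacing)
  }
})
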