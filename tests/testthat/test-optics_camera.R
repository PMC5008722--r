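test_that("PSF width follows the Gaussian approximation and unit conversion", {
  expect_equal(psf_sigma_from_optics(1.2, 520, 100), 0.21 * 520 / 1.2 / 100)
  s1 <- psf_sigma_from_optics(1.2, 520, 100)
  expect_equal(psf_sigma_from_optics(1.2, 520, 200), s1 / 2)
  expect_error(psf_sigma_from_optics(-1, 520, 100), "positive")
  # documented default objective
  expect_equal(optics_config()$numerical_aperture, 1.2)
})

test_that("footprints match dense 2-D quadrature of the Gaussian over pixels", {
  skip_if_not_installed("pracma")
  sigma <- 1.3
  xh <- 5.37; yh <- 6.81
  fp <- render_emitter_footprint(xh, yh, sigma)
  g2 <- function(x, y) {
    exp(-((x - xh)^2 + (y - yh)^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  }
  idx <- order(-fp$v)[1:12] # strongest pixels
  for (i in idx) {
    q <- pracma::quad2d(g2, fp$x[i] - 0.5, fp$x[i] + 0.5,
                        fp$y[i] - 0.5, fp$y[i] + 0.5, n = 48)
    expect_lt(abs(fp$v[i] - q) / q, 1e-9)
  }
})

test_that("footprint symmetry, truncation and limits behave", {
  # emitter at a pixel center: reflection symmetric
  fp <- render_emitter_footprint(5, 5, 1.3)
  m <- matrix(0, 11, 11)
  m[cbind(fp$y + 1, fp$x + 1)] <- fp$v
  expect_equal(m, m[11:1, ], tolerance = 1e-14)
  expect_equal(m, m[, 11:1], tolerance = 1e-14)
  expect_true(all(fp$v > 0 & fp$v < 1))
  expect_lte(sum(fp$v), 1)
  # truncation at 3 sigma loses the 2-D Gaussian tail mass exp(-9/2) ~ 1.1%
  full <- render_emitter_footprint(5.2, 5.4, 1.0, radius_sigma = 8)
  trunc <- render_emitter_footprint(5.2, 5.4, 1.0, radius_sigma = 3)
  loss <- (sum(full$v) - sum(trunc$v)) / sum(full$v)
  expect_lt(loss, 1.5 * exp(-9 / 2))
  expect_gt(loss, 0.5 * exp(-9 / 2))
  # sigma -> 0: all mass in the containing pixel
  tiny <- render_emitter_footprint(5.2, 5.4, 0.01)
  expect_equal(sum(tiny$v), 1, tolerance = 1e-12)
  expect_equal(tiny$v[which.max(tiny$v)], 1, tolerance = 1e-12)
})

test_that("noiseless rendering is linear and additive over emitters", {
  fov <- field_of_view(16, 16, 100)
  opt <- optics_config(psf_sigma_px = 1.3, pixel_size_nm = 100)
  tr <- matrix(1, 1, 5)
  # zero emitters: pure background
  st0 <- render_noiseless_stack(emitter_set(numeric(0), numeric(0), numeric(0), fov),
                                matrix(0, 0, 5), fov, opt, background = 7)
  expect_true(all(st0$frames == 7))
  # one always-on emitter: identical frames, frame sum = brightness * mass
  e1 <- emitter_set(7.2, 8.1, 500, fov)
  st1 <- render_noiseless_stack(e1, tr, fov, opt, background = 0)
  expect_equal(st1$frames[, , 1], st1$frames[, , 5])
  fp <- render_emitter_footprint(7.2, 8.1, 1.3)
  expect_equal(sum(st1$frames[, , 1]), 500 * sum(fp$v), tolerance = 1e-12)
  # superposition is exact
  e2 <- emitter_set(10.6, 4.3, 300, fov)
  st2 <- render_noiseless_stack(e2, tr, fov, opt, background = 0)
  e12 <- emitter_set(c(7.2, 10.6), c(8.1, 4.3), c(500, 300), fov)
  st12 <- render_noiseless_stack(e12, rbind(tr, tr), fov, opt, background = 0)
  expect_equal(st12$frames, st1$frames + st2$frames, tolerance = 1e-12)
  # mismatched trace count errors
  expect_error(render_noiseless_stack(e12, tr, fov, opt), "one state trace per emitter")
})

test_that("camera chain matches the compound Poisson-Gamma-Gaussian law", {
  n <- 1e5
  lambda <- 50; qe <- 0.7; g <- 30; base <- 100; dk <- 3
  clean <- image_stack(array(lambda, c(250, 40, 10)), units = "photons")
  cam <- camera_config(quantum_efficiency = qe, gain = g, dark_noise_sd = dk,
                       baseline = base, frame_time_s = 0.01)
  v <- as.vector(apply_camera(clean, cam, seed = 4)$frames)[1:n]
  m_th <- lambda * qe * g + base
  v_th <- 2 * lambda * qe * g^2 + dk^2
  expect_lt(abs(mean(v) - m_th), 3 * sqrt(v_th / n))
  se_var <- sqrt((mean((v - mean(v))^4) - var(v)^2) / n)
  expect_lt(abs(var(v) - v_th), 3 * se_var)
})

test_that("camera degenerate modes behave", {
  # zero photons, zero dark noise: exactly the baseline
  clean <- image_stack(array(0, c(8, 8, 3)), units = "photons")
  cam <- camera_config(quantum_efficiency = 0.7, gain = 30, dark_noise_sd = 0,
                       baseline = 100, frame_time_s = 0.01)
  expect_true(all(apply_camera(clean, cam, seed = 1)$frames == 100))
  # sCMOS mode: mean = lambda*QE + baseline (gain 1, no Gamma stage)
  clean2 <- image_stack(array(80, c(100, 100, 10)), units = "photons")
  cam2 <- camera_config(quantum_efficiency = 0.9, gain = 1, dark_noise_sd = 0,
                        baseline = 10, frame_time_s = 0.01, em_gain = FALSE)
  v <- as.vector(apply_camera(clean2, cam2, seed = 2)$frames)
  expect_lt(abs(mean(v) - (80 * 0.9 + 10)), 3 * sqrt(72 / length(v)))
})

test_that("full simulation is deterministic and converges to the widefield limit", {
  fov <- field_of_view(16, 16, 100)
  opt <- optics_config(psf_sigma_px = 1.3, pixel_size_nm = 100)
  cam <- camera_config(quantum_efficiency = 0.7, gain = 30, dark_noise_sd = 2,
                       baseline = 100, frame_time_s = 0.01)
  pp <- photophysics_params(0.02, 0.2)
  em <- emitter_set(c(5.5, 10.2), c(8.8, 7.1), 500, fov)
  a <- simulate_stack(emitters = em, photophysics = pp, fov = fov, optics = opt,
                      camera = cam, n_frames = 3000, background = 5, seed = 7)
  b <- simulate_stack(emitters = em, photophysics = pp, fov = fov, optics = opt,
                      camera = cam, n_frames = 3000, background = 5, seed = 7)
  expect_identical(a$frames, b$frames)
  # temporal mean of a long stack correlates with the noiseless time average
  clean <- render_noiseless_stack(em, a$ground_truth$traces, fov, opt, 5)
  expect_gt(cor(as.vector(widefield_image(a)), as.vector(widefield_image(clean))),
            0.99)
})
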