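test_that("the LoG filter removes constants and ramps and peaks at emitters", {
  const <- matrix(7, 32, 32)
  expect_lt(max(abs(log_filter(const, 1.3))), 1e-10)
  ramp <- outer(1:32, 1:32, function(i, j) 2 * i + 3 * j)
  filt <- log_filter(ramp, 1.3)
  inner <- filt[8:24, 8:24] # away from the replicated border
  expect_lt(max(abs(inner)) / max(ramp), 1e-10)
  # single emitter: global max within 1 px of the true position
  fp <- render_emitter_footprint(15.4, 17.8, 1.3)
  img <- matrix(0, 32, 32)
  img[cbind(fp$y + 1, fp$x + 1)] <- 500 * fp$v
  f <- log_filter(img + 20, 1.3)
  pk <- which(f == max(f), arr.ind = TRUE)
  expect_lt(abs(pk[1, "col"] - 1 - 15.4), 1)
  expect_lt(abs(pk[1, "row"] - 1 - 17.8), 1)
})

test_that("segmentation finds isolated emitters and controls false positives", {
  params <- detection_params(log_sigma = 1.3, detection_threshold = 5)
  # pure noise: expected false positives well below 0.1 per frame
  withr::local_seed(2)
  n_fp <- 0
  for (i in 1:50) {
    noise <- matrix(rnorm(64 * 64, 100, 3), 64, 64)
    n_fp <- n_fp + nrow(segment(log_filter(noise, 1.3), params))
  }
  expect_lt(n_fp / 50, 0.1)
  # one bright emitter: exactly one window
  fp <- render_emitter_footprint(20.2, 30.6, 1.3)
  img <- matrix(rnorm(64 * 64, 100, 2), 64, 64)
  img[cbind(fp$y + 1, fp$x + 1)] <- img[cbind(fp$y + 1, fp$x + 1)] + 800 * fp$v
  cand <- segment(log_filter(img, 1.3), params)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$x - 20.2), 1.5)
  # two distinct peaks closer than min_separation: both dropped
  img2 <- matrix(rnorm(64 * 64, 100, 2), 64, 64)
  for (x0 in c(28, 34)) {
    fp <- render_emitter_footprint(x0, 30, 1.3)
    img2[cbind(fp$y + 1, fp$x + 1)] <- img2[cbind(fp$y + 1, fp$x + 1)] + 800 * fp$v
  }
  cand2 <- segment(log_filter(img2, 1.3), params)
  expect_equal(nrow(cand2), 0)
})

test_that("Gaussian fitting recovers noiseless emitters to high accuracy", {
  fp <- render_emitter_footprint(15.30, 17.80, 1.3)
  img <- matrix(0, 40, 40)
  img[cbind(fp$y + 1, fp$x + 1)] <- 1000 * fp$v
  img <- img + 10
  h <- 6
  w <- img[(18 + 1 - h):(18 + 1 + h), (15 + 1 - h):(15 + 1 + h)]
  f <- fit_gaussian(w, x0 = 15 - h, y0 = 18 - h, sigma0 = 1.3)
  expect_lt(abs(f$x_px - 15.30), 1e-3)
  expect_lt(abs(f$y_px - 17.80), 1e-3)
  expect_lt(abs(f$width_px - 1.3), 1e-3)
  expect_lt(abs(f$background - 10), 0.1)
  # emitter exactly at the window center: fitted position at the center
  fpc <- render_emitter_footprint(20, 20, 1.3, radius_sigma = 8)
  imgc <- matrix(0, 40, 40)
  imgc[cbind(fpc$y + 1, fpc$x + 1)] <- 1000 * fpc$v
  wc <- imgc[(21 - 5):(21 + 5), (21 - 5):(21 + 5)]
  fc <- fit_gaussian(wc, x0 = 15, y0 = 15, sigma0 = 1.3)
  expect_equal(fc$x_px, 20, tolerance = 1e-9)
  expect_equal(fc$y_px, 20, tolerance = 1e-9)
  expect_error(fit_gaussian(matrix(1, 3, 3)), "5x5")
})

test_that("localization precision follows the sigma/sqrt(N) photon scaling", {
  withr::local_seed(4)
  sigma <- 1.3
  rmse_at <- function(N, reps) {
    fp <- render_emitter_footprint(10.3, 10.6, sigma, radius_sigma = 5)
    clean <- matrix(0, 21, 21)
    clean[cbind(fp$y + 1, fp$x + 1)] <- N * fp$v
    errs <- replicate(reps, {
      noisy <- matrix(rpois(length(clean), clean), nrow(clean))
      f <- fit_gaussian(noisy[5:17, 5:17], x0 = 4, y0 = 4, sigma0 = sigma)
      sqrt((f$x_px - 10.3)^2 + (f$y_px - 10.6)^2)
    })
    sqrt(mean(errs^2) / 2)
  }
  r250 <- rmse_at(250, 250)
  r1000 <- rmse_at(1000, 250)
  # 4x the photons halve the error (1/sqrt(N) scaling), within 25%
  expect_lt(abs(r250 / r1000 - 2) / 2, 0.25)
  # absolute level: between the weighted-fit bound sigma_a/sqrt(N) and the
  # ~sqrt(2) inefficiency of the unweighted least-squares estimator
  sigma_a <- sqrt(sigma^2 + 1 / 12)
  expect_gt(r1000, 0.9 * sigma_a / sqrt(1000))
  expect_lt(r1000, 1.6 * sigma_a / sqrt(1000))
})

test_that("fit filtering applies the interval rules exactly and idempotently", {
  tab <- do.call(rbind, lapply(1:60, function(i)
    sofisim:::localization_row(i, 5, 5, 500, runif(1, 10, 400),
                               runif(1, 0.4, 4), 10, TRUE, "")))
  out <- filter_fits(tab, expected_width = 1.3, width_tolerance = 0.5,
                     amplitude_bounds = c(50, 350))
  # brute-force application of the two interval rules
  manual <- tab$width_px >= 0.65 & tab$width_px <= 1.95 &
    tab$amplitude >= 50 & tab$amplitude <= 350
  expect_equal(out$accepted, manual)
  expect_true(all(out$reason[!out$accepted] %in% c("width", "amplitude")))
  wide <- which(tab$width_px > 1.95 | tab$width_px < 0.65)
  expect_true(all(out$reason[wide] == "width"))
  # idempotent and order-independent
  again <- filter_fits(out, 1.3, 0.5, c(50, 350))
  expect_equal(again$accepted, out$accepted)
  perm <- sample(nrow(tab))
  out_perm <- filter_fits(tab[perm, ], 1.3, 0.5, c(50, 350))
  expect_equal(out_perm$accepted, manual[perm])
  # exact matches are kept
  ok <- filter_fits(tab, 1.3, 0.5, c(0, Inf))
  expect_true(all(ok$accepted[tab$width_px >= 0.65 & tab$width_px <= 1.95]))
})

test_that("STORM rendering conserves mass and concentrates repeats", {
  tab <- do.call(rbind, lapply(1:7, function(i)
    sofisim:::localization_row(i, 5.2, 8.7, 500, 100, 1.3, 10, TRUE, "")))
  attr(tab, "stack_dim") <- c(16, 16, 7)
  img <- render_storm(tab, upsample = 4, blur_sigma = 0)
  expect_equal(sum(img), 7)          # mass = number of accepted localizations
  expect_equal(max(img), 7)          # all in a single up-sampled bin
  empty <- tab; empty$accepted <- FALSE
  expect_warning(img0 <- render_storm(empty, upsample = 4), "no accepted")
  expect_true(all(img0 == 0))
})

test_that("two sub-diffraction points are separated in the rendered STORM image", {
  fov <- field_of_view(24, 24, 100)
  sep <- 1.2 * 1.3 # below the diffraction limit
  em <- emitter_set(c(11.5 - sep / 2, 11.5 + sep / 2), c(11.5, 11.5), 1500, fov)
  st <- simulate_stack(emitters = em,
                       photophysics = photophysics_params(0.005, 0.4), # sparse
                       fov = fov,
                       optics = optics_config(psf_sigma_px = 1.3, pixel_size_nm = 100),
                       camera = camera_config(quantum_efficiency = 0.9, gain = 1,
                                              dark_noise_sd = 1, baseline = 100,
                                              frame_time_s = 0.01, em_gain = FALSE),
                       n_frames = 3000, background = 2, seed = 17)
  locs <- run_storm(st, detection_params(1.3, detection_threshold = 5))
  img <- render_storm(locs, upsample = 8, blur_sigma = 1)
  pks <- find_local_maxima(img, radius = 4, min_height = 0.35)
  pks <- pks[order(-pks$value), ][1:2, ]
  expect_equal(nrow(pks), 2)
  got_x <- (sort(pks$x) + 0.5) / 8 - 0.5 # bin centers in pixel coordinates
  expect_lt(abs(got_x[1] - (11.5 - sep / 2)), 1 / 8 + 0.05)
  expect_lt(abs(got_x[2] - (11.5 + sep / 2)), 1 / 8 + 0.05)
})
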