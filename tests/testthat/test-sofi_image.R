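test_that("pixel combinations land exactly on their virtual nodes", {
  for (n in 2:7) {
    combos <- pixel_combinations(n, psf_sigma_px = 1.3)
    for (cb in combos) {
      expect_equal(mean(cb$members[, "dx"]), cb$a / n, tolerance = 1e-14)
      expect_equal(mean(cb$members[, "dy"]), cb$b / n, tolerance = 1e-14)
      expect_gt(cb$distance_weight, 1 - 1e-14)
    }
  }
  # order 2: on-grid node is the auto-cumulant (same pixel twice, weight 1);
  # the midway node uses the two horizontal neighbors with weight > 1
  c2 <- pixel_combinations(2, psf_sigma_px = 1.3)
  on_grid <- c2[[1]]
  expect_true(all(on_grid$members == 0))
  expect_equal(on_grid$distance_weight, 1)
  mid <- Filter(function(cb) cb$a == 1 && cb$b == 0, c2)[[1]]
  expect_equal(sort(mid$members[, "dx"]), c(0L, 1L))
  expect_true(all(mid$members[, "dy"] == 0))
  expect_gt(mid$distance_weight, 1)
  expect_error(pixel_combinations(3, 1.3, upsample = 2), "divide")
})

test_that("cumulant image values equal the per-trace joint cumulant times the distance weight", {
  # independent route: extract member pixel traces and call joint_cumulant
  st <- make_single_emitter_stack(400, sigma = 1.5, fov_px = 12, seed = 21)
  for (n in c(2, 3)) {
    ci <- cross_cumulant_image(st, n)
    combos <- pixel_combinations(n, psf_sigma_px = 1.5)
    for (cb in combos[c(1, length(combos))]) {
      x0 <- 5L; y0 <- 6L # arbitrary interior physical pixel
      traces <- lapply(seq_len(n), function(i)
        st$frames[y0 + 1 + cb$members[i, "dy"], x0 + 1 + cb$members[i, "dx"], ])
      expected <- cb$distance_weight * joint_cumulant(traces)
      got <- ci$values[n * y0 + cb$b + 1, n * x0 + cb$a + 1]
      expect_equal(got, expected, tolerance = 1e-10)
    }
  }
})

test_that("stationary background is suppressed and cross-pixels reduce noise", {
  fov <- field_of_view(10, 10, 100)
  opt <- optics_config(psf_sigma_px = 1.3, pixel_size_nm = 100)
  em <- emitter_set(numeric(0), numeric(0), numeric(0), fov)
  tr <- structure(list(fractions = matrix(0, 0, 800)), class = "state_traces")
  clean <- render_noiseless_stack(em, tr, fov, opt, background = 50)
  # noiseless stationary background: raw cumulant exactly zero
  ci0 <- suppressWarnings(cross_cumulant_image(clean, 2))
  expect_equal(max(abs(ci0$values)), 0)
  # with camera noise, only the auto-cumulant (on-grid) pixels carry the
  # uncorrelated shot noise; the interleaved cross-pixels suppress it
  cam <- camera_config(quantum_efficiency = 0.9, gain = 1, dark_noise_sd = 0.5,
                       baseline = 100, frame_time_s = 0.01, em_gain = FALSE)
  st <- apply_camera(clean, cam, seed = 2)
  ci2 <- cross_cumulant_image(st, 2)
  on_grid <- ci2$values[seq(1, 19, 2), seq(1, 19, 2)]
  off_grid <- ci2$values[seq(2, 18, 2), seq(2, 18, 2)]
  # off-grid expectation is 0; its finite-sample spread is var/sqrt(T),
  # far below the on-grid shot-noise variance
  expect_lt(max(abs(off_grid)), 0.25 * mean(on_grid))
  expect_gt(mean(on_grid), 0.5 * 45) # auto pixels see the shot-noise variance
})

test_that("adding a constant offset to every pixel leaves raw cumulants unchanged", {
  st <- make_single_emitter_stack(300, fov_px = 10, seed = 31)
  st_shift <- st
  st_shift$frames <- st$frames + 1e4
  for (n in 2:4) {
    a <- cross_cumulant_image(st, n)$values
    b <- cross_cumulant_image(st_shift, n)$values
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-8)
  }
})

test_that("cumulant of the sum of independent stacks is the sum of cumulants", {
  sa <- make_single_emitter_stack(2000, fov_px = 12, seed = 41, x = 4.2, y = 6.1,
                                  background = 0)
  sb <- make_single_emitter_stack(2000, fov_px = 12, seed = 57, x = 8.3, y = 5.4,
                                  background = 0)
  joint <- sa
  joint$frames <- sa$frames + sb$frames
  ka <- cross_cumulant_image(sa, 2)$values
  kb <- cross_cumulant_image(sb, 2)$values
  kj <- cross_cumulant_image(joint, 2)$values
  # agreement within sampling error: compare at the two emitter peaks
  for (pk in list(ka, kb)) {
    i <- which.max(abs(pk))
    expect_lt(abs(kj[i] - (ka[i] + kb[i])) / max(abs(ka[i] + kb[i])), 0.15)
  }
})

test_that("flattening equalizes sub-grids without introducing sign changes", {
  # uniform dense field: sub-grid means must agree after flattening
  fov <- field_of_view(16, 16, 100)
  em <- generate_random_emitters(fov, 400, 500, seed = 3)
  st <- simulate_stack(emitters = em,
                       photophysics = photophysics_params(0.02, 0.2),
                       fov = fov,
                       optics = optics_config(psf_sigma_px = 1.3, pixel_size_nm = 100),
                       camera = camera_config(quantum_efficiency = 0.9, gain = 1,
                                              dark_noise_sd = 1, baseline = 100,
                                              frame_time_s = 0.01, em_gain = FALSE),
                       n_frames = 1000, background = 2, seed = 5)
  raw <- cross_cumulant_image(st, 2)
  fl <- flatten(raw)
  valid <- !fl$border_mask
  sub <- interaction((row(fl$values) - 1) %% 2, (col(fl$values) - 1) %% 2)
  means <- tapply(abs(fl$values[valid]), sub[valid], mean)
  expect_lt(diff(range(means)) / mean(means), 0.05)
  # positive pixelwise rescaling: no new sign changes
  expect_equal(sign(fl$values[valid]), sign(raw$values[valid]))
  # idempotence on an already flat image (up to global scale)
  fl2in <- fl; fl2in$stage <- "raw"
  fl2 <- flatten(fl2in)
  ratio <- fl2$values[valid] / fl$values[valid]
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-6)
  # all-zero input returned unchanged
  z <- cumulant_image(matrix(0, 8, 8), 2, "raw", 2)
  expect_equal(flatten(z)$values, z$values)
})

test_that("Richardson-Lucy deconvolution sharpens peaks and fixes flat images", {
  # delta input with matching kernel: peak strictly increases per iteration
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  blur <- EBImage::filter2(img, sofisim:::gaussian_kernel(2), boundary = "replicate")
  ci <- cumulant_image(blur, order = 4, stage = "flattened", upsample = 4,
                       psf_sigma_px = 2 * sqrt(4) / 4)
  peaks <- vapply(1:5, function(it)
    max(deconvolve(ci, iterations = it)$values), numeric(1))
  expect_true(all(diff(peaks) > 0))
  # flat input is a fixed point
  flat <- cumulant_image(matrix(5, 24, 24), 2, "flattened", 2, psf_sigma_px = 1.3)
  out <- deconvolve(flat, iterations = 5)
  expect_lt(diff(range(out$values)) / 5, 1e-6)
  expect_error(deconvolve(flat, iterations = 0), "positive")
})

test_that("deconvolution narrows an isolated emitter's cumulant spot", {
  st <- make_single_emitter_stack(4000, sigma = 2, seed = 61)
  raw <- cross_cumulant_image(st, 4)
  fl <- flatten(raw)
  dec <- deconvolve(fl, iterations = 10)
  w_before <- sofisim:::fit_gaussian_peak(fl$values)$sigma
  w_after <- sofisim:::fit_gaussian_peak(dec$values)$sigma
  expect_lt(w_after, w_before)
})

test_that("linearization takes the n-th root of the magnitude", {
  ci <- cumulant_image(matrix(c(16, 0, -16, 81), 2, 2), order = 4,
                       stage = "deconvolved", upsample = 1)
  lin <- linearize(ci)
  expect_equal(lin$values, matrix(c(2, 0, 2, 3), 2, 2))
  expect_true(all(lin$values >= 0))
})

test_that("linearization restores linear brightness ratios across emitters", {
  fov <- field_of_view(20, 12, 100)
  em <- emitter_set(c(5, 14.5), c(5.5, 5.5), c(400, 800), fov) # ratio 2
  st <- simulate_stack(emitters = em,
                       photophysics = photophysics_params(0.02, 0.2),
                       fov = fov,
                       optics = optics_config(psf_sigma_px = 1.2, pixel_size_nm = 100),
                       camera = camera_config(quantum_efficiency = 0.9, gain = 1,
                                              dark_noise_sd = 1, baseline = 100,
                                              frame_time_s = 0.01, em_gain = FALSE),
                       n_frames = 8000, background = 1, seed = 9)
  raw <- cross_cumulant_image(st, 3)
  v <- raw$values
  left <- max(abs(v[, 1:(ncol(v) / 2)]))
  right <- max(abs(v[, (ncol(v) / 2 + 1):ncol(v)]))
  expect_equal(right / left, 8, tolerance = 0.35) # epsilon^3 response
  lin <- linearize(flatten(raw))
  vl <- lin$values
  left_l <- max(vl[, 1:(ncol(vl) / 2)])
  right_l <- max(vl[, (ncol(vl) / 2 + 1):ncol(vl)])
  expect_equal(right_l / left_l, 2, tolerance = 0.15)
})

test_that("the bSOFI pipeline emits one image per order plus the widefield", {
  st <- make_single_emitter_stack(300, fov_px = 10, seed = 71)
  res <- bsofi_pipeline(st, orders = c(2, 3))
  expect_named(res$orders, c("order2", "order3"))
  expect_equal(dim(res$widefield), c(10, 10))
  expect_s3_class(res$orders$order2, "cumulant_image")
  expect_equal(res$orders$order2$stage, "linearized")
  expect_equal(dim(res$orders$order3$values), c(30, 30))
  empty <- image_stack(array(1, c(10, 10, 1)))
  expect_error(bsofi_pipeline(empty), "at least 2 frames")
})
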