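#' Camera configuration
#'
#' Parameterizes the detection chain applied to expected photon counts:
#' Poisson shot noise at rate `expected * quantum_efficiency`, stochastic
#' electron-multiplying gain modelled as a Gamma distribution with shape
#' equal to the number of registered photons and scale `gain`, additive
#' Gaussian dark noise, and a constant digital baseline.
#'
#' @param quantum_efficiency detection probability per photon, in (0, 1].
#' @param gain camera gain, electrons (digital units) per photoelectron. With
#'   `em_gain = FALSE` the Gamma stage is bypassed and counts are scaled
#'   deterministically by `gain` (sCMOS-like camera).
#' @param dark_noise_sd standard deviation of the Gaussian dark/readout
#'   noise, digital units.
#' @param baseline constant digital offset added to every pixel.
#' @param frame_time_s exposure time per frame, seconds.
#' @param em_gain logical; `TRUE` (default) applies the stochastic Gamma
#'   amplification of an EMCCD, `FALSE` the deterministic scaling of an
#'   sCMOS camera.
#' @param quantize logical; round the output to integer digital units.
#' @return an object of class `camera_config`.
#' @export
#' @examples
#' camera_config(quantum_efficiency = 0.7, gain = 30, dark_noise_sd = 2,
#'               baseline = 100, frame_time_s = 0.01)
camera_config <- function(quantum_efficiency = 0.9, gain = 1,
                          dark_noise_sd = 1, baseline = 100,
                          frame_time_s = 0.01, em_gain = TRUE,
                          quantize = FALSE) {
  if (quantum_efficiency <= 0 || quantum_efficiency > 1)
    stop("quantum_efficiency must be in (0, 1]", call. = FALSE)
  if (gain <= 0 || frame_time_s <= 0)
    stop("gain and frame_time_s must be positive", call. = FALSE)
  if (dark_noise_sd < 0 || baseline < 0)
    stop("dark_noise_sd and baseline must be nonnegative", call. = FALSE)
  structure(list(quantum_efficiency = quantum_efficiency, gain = gain,
                 dark_noise_sd = dark_noise_sd, baseline = baseline,
                 frame_time_s = frame_time_s, em_gain = isTRUE(em_gain),
                 quantize = isTRUE(quantize)),
            class = "camera_config")
}

#' Image stack container
#'
#' A `T`-frame stack of `H x W` images with acquisition metadata. Frames are
#' stored as an `H x W x T` array indexed `[y + 1, x + 1, t]` in the
#' zero-based pixel coordinates of [field_of_view()].
#'
#' @param frames `H x W x T` numeric array (a single matrix is promoted to
#'   one frame).
#' @param fov a [field_of_view()] (optional but recommended).
#' @param optics,camera optional [optics_config()] / [camera_config()].
#' @param units `"photons"` (expected photons) or `"du"` (digital units).
#' @param seed seed used to generate the stack, if any.
#' @param ground_truth optional list carrying the generating emitter set and
#'   state traces.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, fov = NULL, optics = NULL, camera = NULL,
                        units = "du", seed = NULL, ground_truth = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3)
  if (any(!is.finite(frames))) stop("frames must be finite", call. = FALSE)
  if (!is.null(fov) && (dim(frames)[1] != fov$height_px || dim(frames)[2] != fov$width_px))
    stop("frame dimensions do not match the field of view", call. = FALSE)
  structure(list(frames = frames, fov = fov, optics = optics, camera = camera,
                 units = units, seed = seed, ground_truth = ground_truth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px [%s]\n",
              d[3], d[1], d[2], x$units))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Apply the camera noise chain to a noiseless stack
#'
#' Per pixel and frame, with expected photon count `lambda`:
#' `n ~ Poisson(lambda * QE)`; for the EMCCD mode the amplified charge is
#' `Gamma(shape = n, scale = gain)` (zero when no photon was registered),
#' for the sCMOS mode it is `n * gain`; Gaussian dark noise of standard
#' deviation `dark_noise_sd` and the baseline are then added, and the result
#' is clipped at zero (optionally rounded to integers).
#'
#' @param noiseless an `image_stack` in expected-photon units.
#' @param camera a [camera_config()].
#' @param seed integer seed.
#' @return an `image_stack` in digital units.
#' @export
apply_camera <- function(noiseless, camera, seed) {
  if (!inherits(noiseless, "image_stack")) stop("need an image_stack", call. = FALSE)
  lam <- noiseless$frames * camera$quantum_efficiency
  if (any(lam < 0)) stop("expected photon counts must be nonnegative", call. = FALSE)
  out <- with_stream_seed(seed, "camera", {
    n <- rpois(length(lam), lam)
    charge <- if (camera$em_gain) {
      ch <- numeric(length(n))
      pos <- n > 0
      ch[pos] <- rgamma(sum(pos), shape = n[pos], scale = camera$gain)
      ch
    } else n * camera$gain
    v <- charge + camera$baseline
    if (camera$dark_noise_sd > 0) v <- v + rnorm(length(v), 0, camera$dark_noise_sd)
    v
  })
  out <- pmax(out, 0)
  if (camera$quantize) out <- round(out)
  image_stack(array(out, dim = dim(noiseless$frames)), fov = noiseless$fov,
              optics = noiseless$optics, camera = camera, units = "du",
              seed = seed, ground_truth = noiseless$ground_truth)
}

#' Simulate a complete acquisition
#'
#' Composes the full forward model: emitter placement, two-state Markov
#' blinking with bleaching, pixel-integrated Gaussian PSF rendering with
#' stationary background, and the camera noise chain. The generating emitter
#' set and state traces are stored in the stack's `ground_truth`.
#'
#' @param emitters an [emitter_set()], or `NULL` to generate one from
#'   `pattern`.
#' @param pattern a [pattern_spec()] (used when `emitters` is `NULL`).
#' @param brightness expected detected photons per fully-on frame (used when
#'   generating emitters from `pattern`).
#' @param photophysics a [photophysics_params()].
#' @param fov a [field_of_view()].
#' @param optics an [optics_config()].
#' @param camera a [camera_config()].
#' @param n_frames number of frames.
#' @param background expected background photons per pixel per frame.
#' @param seed integer base seed; stage seeds are derived with
#'   [split_seed()].
#' @param noise logical; `FALSE` returns the noiseless expected-photon stack.
#' @return an `image_stack` in digital units (photon units when
#'   `noise = FALSE`).
#' @export
#' @examples
#' fov <- field_of_view(16, 16, 100)
#' st <- simulate_stack(pattern = pattern_spec("points",
#'                        geometry = cbind(7.5, 7.5)),
#'                      brightness = 300,
#'                      photophysics = photophysics_params(0.02, 0.2),
#'                      fov = fov, optics = optics_config(pixel_size_nm = 100),
#'                      camera = camera_config(), n_frames = 50, seed = 1)
simulate_stack <- function(emitters = NULL, pattern = NULL, brightness = 500,
                           photophysics, fov, optics, camera,
                           n_frames, background = 0, seed, noise = TRUE) {
  if (is.null(emitters)) {
    if (is.null(pattern)) stop("provide emitters or a pattern", call. = FALSE)
    emitters <- generate_pattern_emitters(fov, pattern, brightness, seed)
  }
  traces <- simulate_state_traces(photophysics, camera$frame_time_s, n_frames,
                                  nrow(emitters), seed)
  clean <- render_noiseless_stack(emitters, traces, fov, optics, background)
  clean$ground_truth <- list(emitters = emitters, traces = traces,
                             photophysics = photophysics)
  clean$seed <- seed
  if (!noise) return(clean)
  apply_camera(clean, camera, seed)
}

#' Temporal mean (widefield) image of a stack
#'
#' The diffraction-limited baseline against which super-resolved images are
#' compared.
#'
#' @param stack an `image_stack`.
#' @return an `H x W` matrix.
#' @export
widefield_image <- function(stack) {
  rowMeans(stack$frames, dims = 2)
}
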