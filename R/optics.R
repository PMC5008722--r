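#' Optical configuration
#'
#' The point-spread function (PSF) is a symmetric 2-D Gaussian whose standard
#' deviation derives from the numerical aperture, emission wavelength and
#' camera pixel size via the widefield Gaussian approximation
#' `sigma_nm = 0.21 * lambda / NA`; `psf_sigma_px` can also be set directly.
#'
#' @param numerical_aperture dimensionless; typical water/oil immersion
#'   objectives fall in (0, 1.5].
#' @param emission_wavelength_nm emission wavelength, nm (300-900 nm is the
#'   documented visible/near-IR range).
#' @param pixel_size_nm camera pixel size at the sample plane, nm.
#' @param psf_sigma_px optional direct override of the PSF standard deviation
#'   in pixel units. Must exceed 0.5 px: fluctuation imaging requires the PSF
#'   to extend over several camera pixels.
#' @return an object of class `optics_config`.
#' @export
#' @examples
#' optics_config(1.2, 520, 100)
optics_config <- function(numerical_aperture = 1.2, emission_wavelength_nm = 520,
                          pixel_size_nm = 100, psf_sigma_px = NULL) {
  if (numerical_aperture <= 0) stop("numerical aperture must be positive", call. = FALSE)
  if (emission_wavelength_nm <= 0 || pixel_size_nm <= 0)
    stop("wavelength and pixel size must be positive", call. = FALSE)
  if (is.null(psf_sigma_px)) {
    psf_sigma_px <- psf_sigma_from_optics(numerical_aperture,
                                          emission_wavelength_nm, pixel_size_nm)
  }
  if (psf_sigma_px <= 0.5)
    stop("psf_sigma_px must exceed 0.5 px (PSF must span several pixels)",
         call. = FALSE)
  structure(list(numerical_aperture = numerical_aperture,
                 emission_wavelength_nm = emission_wavelength_nm,
                 pixel_size_nm = pixel_size_nm,
                 psf_sigma_px = psf_sigma_px),
            class = "optics_config")
}

#' PSF standard deviation from optical parameters
#'
#' Gaussian approximation of the widefield PSF:
#' `sigma_nm = 0.21 * lambda / NA`, converted to pixel units.
#'
#' @param na numerical aperture.
#' @param wavelength_nm emission wavelength, nm.
#' @param pixel_size_nm camera pixel size at the sample plane, nm.
#' @return PSF standard deviation in pixel units.
#' @export
#' @examples
#' psf_sigma_from_optics(1.2, 520, 100) # 0.91 px
psf_sigma_from_optics <- function(na, wavelength_nm, pixel_size_nm) {
  if (na <= 0 || wavelength_nm <= 0 || pixel_size_nm <= 0)
    stop("optical parameters must be positive", call. = FALSE)
  0.21 * wavelength_nm / na / pixel_size_nm
}

#' Pixel-integrated Gaussian footprint of one emitter
#'
#' The contribution of an emitter at continuous position `(x_hat, y_hat)` to
#' pixel `(x, y)` is the product of the 1-D Gaussian masses integrated over
#' the pixel extent,
#' `v = [Phi((x - x_hat + 1/2)/sigma) - Phi((x - x_hat - 1/2)/sigma)] *
#'      [Phi((y - y_hat + 1/2)/sigma) - Phi((y - y_hat - 1/2)/sigma)]`,
#' evaluated for every pixel whose center lies within `3 sigma` of the
#' emitter (truncation keeps footprints sparse; the mass lost is below 0.3%
#' for sigma >= 1).
#'
#' @param x_hat,y_hat emitter position, pixel units (origin at the center of
#'   pixel (0, 0)).
#' @param sigma PSF standard deviation, pixels.
#' @param radius_sigma truncation radius in units of sigma (default 3).
#' @return a data frame with zero-based integer pixel indices `x`, `y` and
#'   weights `v` in (0, 1); the total weight never exceeds 1.
#' @export
render_emitter_footprint <- function(x_hat, y_hat, sigma, radius_sigma = 3) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  r <- radius_sigma * sigma
  xs <- seq(floor(x_hat - r), ceiling(x_hat + r))
  ys <- seq(floor(y_hat - r), ceiling(y_hat + r))
  ix <- pnorm((xs - x_hat + 0.5) / sigma) - pnorm((xs - x_hat - 0.5) / sigma)
  iy <- pnorm((ys - y_hat + 0.5) / sigma) - pnorm((ys - y_hat - 0.5) / sigma)
  g <- expand.grid(x = xs, y = ys)
  v <- as.vector(outer(ix, iy))
  keep <- (g$x - x_hat)^2 + (g$y - y_hat)^2 <= r^2
  # the containing pixel always belongs to the support (sigma -> 0 limit)
  keep <- keep | (g$x == floor(x_hat + 0.5) & g$y == floor(y_hat + 0.5))
  data.frame(x = g$x[keep], y = g$y[keep], v = v[keep])
}

# Sparse footprint matrix: pixels (H*W, column-major over y then x... we use
# linear index = y + H*x + 1, i.e. frames are H x W matrices with rows = y).
footprint_matrix <- function(emitters, fov, sigma, radius_sigma = 3) {
  H <- fov$height_px; W <- fov$width_px
  ii <- list(); jj <- list(); vv <- list()
  for (k in seq_len(nrow(emitters))) {
    fp <- render_emitter_footprint(emitters$x[k], emitters$y[k], sigma, radius_sigma)
    keep <- fp$x >= 0 & fp$x < W & fp$y >= 0 & fp$y < H
    fp <- fp[keep, , drop = FALSE]
    ii[[k]] <- fp$y + H * fp$x + 1L
    jj[[k]] <- rep(k, nrow(fp))
    vv[[k]] <- fp$v
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(H * W, nrow(emitters)))
}

#' Render a noiseless image stack (expected-photon units)
#'
#' Frame `t`, pixel `(x, y)` receives
#' `sum_k brightness_k * v_k(x, y) * s_k(t) + background`, i.e. the
#' superposition of all emitter footprints weighted by the per-frame emissive
#' fraction, plus a stationary background. Linear in brightness and additive
#' over emitters.
#'
#' @param emitters an [emitter_set()].
#' @param traces a `state_traces` object (one trace per emitter) or an
#'   emitters x frames matrix of emissive fractions.
#' @param fov a [field_of_view()].
#' @param optics an [optics_config()].
#' @param background stationary background in expected photons per pixel per
#'   frame; a scalar or an `H x W` matrix.
#' @return an `image_stack` in expected-photon units.
#' @export
render_noiseless_stack <- function(emitters, traces, fov, optics, background = 0) {
  fr <- if (inherits(traces, "state_traces")) traces$fractions else as.matrix(traces)
  if (nrow(fr) != nrow(emitters))
    stop("need exactly one state trace per emitter", call. = FALSE)
  H <- fov$height_px; W <- fov$width_px; T_ <- ncol(fr)
  if (is.matrix(background)) {
    if (!all(dim(background) == c(H, W)))
      stop("background image must match the field of view", call. = FALSE)
    bg <- as.vector(background)
  } else bg <- rep(background, H * W)
  if (nrow(emitters) > 0) {
    Fm <- footprint_matrix(emitters, fov, optics$psf_sigma_px)
    px <- as.matrix(Fm %*% (emitters$brightness * fr))
  } else {
    px <- matrix(0, H * W, T_)
  }
  px <- px + bg
  image_stack(array(px, dim = c(H, W, T_)), fov = fov, optics = optics,
              units = "photons")
}
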