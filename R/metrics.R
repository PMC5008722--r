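#' Iterative threshold selection (Ridler-Calvard)
#'
#' Starting from the image mean, iterates
#' `T <- (mean(values <= T) + mean(values > T)) / 2` until the change falls
#' below `1e-6` of the intensity range. Splits an image into signal and
#' background masks; for a two-level image the fixed point is the midpoint
#' of the two levels, and an affine rescaling of the image rescales the
#' threshold identically.
#'
#' @param image numeric matrix (or vector).
#' @return list with `threshold`, `signal_mask`, `background_mask`.
#' @export
iterative_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("image is constant; no threshold exists", call. = FALSE)
  thr <- mean(image)
  for (i in 1:500) {
    lo <- image[image <= thr]; hi <- image[image > thr]
    if (length(lo) == 0 || length(hi) == 0) break
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < 1e-6 * diff(rng)) { thr <- new_thr; break }
    thr <- new_thr
  }
  list(threshold = thr, signal_mask = image > thr, background_mask = image <= thr)
}

#' Estimate SNR and signal-to-background ratio of a stack
#'
#' Works on the temporal-average image: signal/background masks come from
#' [iterative_threshold()]; `i_peak` is the maximum of the average image and
#' `B` the mean over the background mask, giving `S/B = (i_peak - B) / B`.
#' The noise level is the pooled temporal standard deviation over background
#' pixels, and `SNR_db = 20 log10((i_peak - B) / sigma_noise)`. A
#' zero-variance background yields `snr_db = Inf` rather than an error.
#'
#' @param stack an `image_stack` (at least 2 frames).
#' @return list of class `quality_metrics`: `snr_db`, `s_over_b`, `i_peak`,
#'   `background`, `noise_sd`.
#' @export
estimate_snr_sb <- function(stack) {
  if (!inherits(stack, "image_stack")) stop("need an image_stack", call. = FALSE)
  T_ <- n_frames(stack)
  if (T_ < 2) stop("need at least 2 frames", call. = FALSE)
  avg <- widefield_image(stack)
  masks <- iterative_threshold(avg)
  i_peak <- max(avg)
  B <- mean(avg[masks$background_mask])
  s_over_b <- (i_peak - B) / B
  px <- matrix(stack$frames, nrow = length(avg), ncol = T_)
  bgpix <- which(masks$background_mask)
  vars <- apply(px[bgpix, , drop = FALSE], 1, var)
  noise_sd <- sqrt(mean(vars))
  snr_db <- if (noise_sd == 0) Inf else 20 * log10((i_peak - B) / noise_sd)
  structure(list(snr_db = snr_db, s_over_b = s_over_b, i_peak = i_peak,
                 background = B, noise_sd = noise_sd),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("<quality_metrics> SNR = %.1f dB, S/B = %.2f, I_peak = %.1f\n",
              x$snr_db, x$s_over_b, x$i_peak))
  invisible(x)
}

#' Estimate the on-time ratio from traces or an image stack
#'
#' For simulated data with ground truth (`state_traces` or a fraction
#' matrix), the estimate is total on-time over total off-time pooled across
#' emitters. For an image stack, the time traces of the most strongly
#' fluctuating pixels (candidate single-emitter pixels) are thresholded at
#' the midpoint between their on and off levels ([iterative_threshold()]),
#' and the pooled duty ratio time-above / time-below is returned.
#'
#' @param x a `state_traces` object, an emitters-by-frames matrix of emissive
#'   fractions, or an `image_stack`.
#' @param n_pixels number of candidate pixels used in image mode.
#' @return the estimated ratio (`Inf` if no off-time was observed).
#' @export
estimate_on_time_ratio <- function(x, n_pixels = 10) {
  if (inherits(x, "state_traces") || is.matrix(x)) {
    fr <- if (inherits(x, "state_traces")) x$fractions else x
    if (length(fr) == 0) stop("no traces supplied", call. = FALSE)
    on_t <- sum(fr)
    off_t <- length(fr) - on_t
    if (off_t <= 0) return(Inf)
    return(on_t / off_t)
  }
  if (inherits(x, "image_stack")) {
    T_ <- n_frames(x)
    px <- matrix(x$frames, ncol = T_)
    vars <- apply(px, 1, var)
    cand <- order(vars, decreasing = TRUE)[seq_len(min(n_pixels, nrow(px)))]
    on_t <- 0; off_t <- 0
    for (i in cand) {
      tr <- px[i, ]
      if (diff(range(tr)) == 0) next
      thr <- iterative_threshold(tr)$threshold
      on_t <- on_t + sum(tr > thr)
      off_t <- off_t + sum(tr <= thr)
    }
    if (on_t + off_t == 0) stop("no qualifying pixel traces found", call. = FALSE)
    if (off_t == 0) return(Inf)
    return(on_t / off_t)
  }
  stop("x must be state traces, a fraction matrix, or an image_stack", call. = FALSE)
}

bilinear_sample <- function(image, x, y) {
  # zero-based continuous coordinates; pixel (0,0) at image[1,1]
  H <- nrow(image); W <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 0), W - 2); y0 <- pmin(pmax(y0, 0), H - 2)
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Full width at half maximum of a peak profile
#'
#' Samples the image along a line through a point by bilinear interpolation,
#' finds the peak, subtracts the local background (the minimum of the
#' profile) and reports the linearly interpolated full width at half the
#' remaining height. Invariant to affine intensity rescaling.
#'
#' @param image numeric matrix.
#' @param through_point numeric `c(x, y)` in zero-based pixel coordinates.
#' @param direction numeric `c(dx, dy)`; need not be normalized.
#' @param half_length profile half-length in pixels (default: to the image
#'   border).
#' @param step sampling step along the profile, pixels.
#' @return width in pixels.
#' @export
measure_fwhm <- function(image, through_point, direction = c(1, 0),
                         half_length = NULL, step = 0.05) {
  dirn <- direction / sqrt(sum(direction^2))
  if (is.null(half_length)) half_length <- min(dim(image)) / 2 - 1
  s <- seq(-half_length, half_length, by = step)
  xs <- through_point[1] + s * dirn[1]
  ys <- through_point[2] + s * dirn[2]
  ok <- xs >= 0 & xs <= ncol(image) - 1 & ys >= 0 & ys <= nrow(image) - 1
  s <- s[ok]; prof <- bilinear_sample(image, xs[ok], ys[ok])
  ipk <- which.max(prof)
  bg <- min(prof)
  half <- bg + (prof[ipk] - bg) / 2
  above <- prof >= half
  if (!any(above[-ipk])) stop("no half-maximum crossing found", call. = FALSE)
  cross <- function(i, j) { # linear interpolation between samples i (below) and j (above)
    s[i] + (half - prof[i]) / (prof[j] - prof[i]) * (s[j] - s[i])
  }
  left <- ipk; while (left > 1 && prof[left - 1] >= half) left <- left - 1
  right <- ipk; while (right < length(prof) && prof[right + 1] >= half) right <- right + 1
  if (left == 1 || right == length(prof))
    stop("no half-maximum crossing found within the profile", call. = FALSE)
  cross(right + 1, right) - cross(left - 1, left)
}

# Fit a symmetric 2D (sampled) Gaussian to an image peak; used for width
# measurements on cumulant images. Returns center (zero-based), sigma.
fit_gaussian_peak <- function(image, mask = NULL) {
  v <- abs(image)
  if (!is.null(mask)) v[!mask] <- 0
  pk <- which.max(v)
  py <- (pk - 1) %% nrow(v); px <- (pk - 1) %/% nrow(v)
  ys <- seq_len(nrow(v)) - 1; xs <- seq_len(ncol(v)) - 1
  tot <- sum(v)
  start <- c(A = max(v), x = px, y = py, s = max(1, sqrt(tot / (2 * pi * max(v)))), b = 0)
  res_fun <- function(par) {
    g <- par[1] * exp(-((outer(ys, xs, function(y, x)
      (x - par[2])^2 + (y - par[3])^2)) / (2 * par[4]^2))) + par[5]
    as.vector(g - v)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = res_fun,
                            lower = c(0, -1, -1, 0.05, -Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  list(x = unname(p[2]), y = unname(p[3]), sigma = unname(p[4]),
       amplitude = unname(p[1]), offset = unname(p[5]))
}

#' Find local maxima of an image
#'
#' A pixel is a local maximum if it is strictly greater than all neighbors
#' within the given radius and exceeds `min_height` (relative to the image
#' maximum). Used for resolvability checks (how many peaks does a
#' super-resolved image show where the widefield shows one?).
#'
#' @param image numeric matrix.
#' @param radius neighborhood radius in pixels.
#' @param min_height minimum peak height as a fraction of the image maximum.
#' @return data frame of zero-based peak coordinates `x`, `y` and `value`.
#' @export
find_local_maxima <- function(image, radius = 2L, min_height = 0.2) {
  H <- nrow(image); W <- ncol(image)
  thr <- min_height * max(image)
  peaks <- list()
  for (j in seq_len(W)) for (i in seq_len(H)) {
    v <- image[i, j]
    if (v < thr) next
    r0 <- max(1, i - radius):min(H, i + radius)
    c0 <- max(1, j - radius):min(W, j + radius)
    nb <- image[r0, c0]
    if (v >= max(nb) && sum(nb == v) == 1) {
      peaks[[length(peaks) + 1L]] <- c(x = j - 1, y = i - 1, value = v)
    }
  }
  if (!length(peaks)) return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  as.data.frame(do.call(rbind, peaks))
}
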