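#' Detection parameters for the basic STORM pipeline
#'
#' @param log_sigma width (pixels) of the Laplacian-of-Gaussian detection
#'   kernel; match it to the PSF standard deviation.
#' @param detection_threshold threshold in multiples of the robust
#'   (median-absolute-deviation based) noise standard deviation of the
#'   filtered frame.
#' @param min_separation_px minimal separation between candidate peaks;
#'   pairs closer than this are both dropped (basic STORM is a sparse-regime
#'   algorithm; overlapping emitters are left to high-density methods).
#' @param window_half_px half-size of the square fitting window; default
#'   `max(4, ceiling(3 * log_sigma))`.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(log_sigma, detection_threshold = 5,
                             min_separation_px = NULL, window_half_px = NULL) {
  if (log_sigma <= 0 || detection_threshold <= 0)
    stop("log_sigma and detection_threshold must be positive", call. = FALSE)
  if (is.null(window_half_px)) window_half_px <- max(4L, ceiling(3 * log_sigma))
  if (is.null(min_separation_px)) min_separation_px <- 2 * window_half_px
  structure(list(log_sigma = log_sigma,
                 detection_threshold = detection_threshold,
                 min_separation_px = min_separation_px,
                 window_half_px = as.integer(window_half_px)),
            class = "detection_params")
}

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(3.5 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  gxx <- g * (x^2 / sigma^4 - 1 / sigma^2)
  k <- -(outer(gxx, g) + outer(g, gxx)) # negated LoG: blobs become maxima
  k <- k / sum(abs(k))
  k - mean(k) # exactly zero-sum: constants (and, by symmetry, ramps) vanish
}

#' Laplacian-of-Gaussian filter of a frame
#'
#' Applies a negated, zero-sum LoG kernel so that diffraction-limited blobs
#' become positive peaks while constant background and linear intensity
#' trends are removed.
#'
#' @param frame numeric matrix.
#' @param log_sigma kernel width in pixels.
#' @return filtered matrix of the same size.
#' @export
log_filter <- function(frame, log_sigma) {
  if (log_sigma <= 0) stop("log_sigma must be positive", call. = FALSE)
  EBImage::filter2(frame, log_kernel(log_sigma), boundary = "replicate")
}

#' Segment a filtered frame into candidate emitter windows
#'
#' Thresholds the LoG-filtered frame at `detection_threshold` robust noise
#' standard deviations (MAD-based), labels connected regions, and returns one
#' square window per region centered on the region's peak. Windows whose
#' peaks are closer than `min_separation_px` are both dropped, as are windows
#' that do not fit inside the frame.
#'
#' @param filtered LoG-filtered frame (from [log_filter()]).
#' @param params a [detection_params()].
#' @return data frame with zero-based peak coordinates `x`, `y` and the
#'   window half-size `half`; zero rows if nothing is detected.
#' @export
segment <- function(filtered, params) {
  noise_sd <- mad(filtered)
  if (noise_sd == 0) noise_sd <- sd(filtered)
  mask <- filtered > params$detection_threshold * noise_sd
  if (!any(mask)) return(data.frame(x = integer(0), y = integer(0), half = integer(0)))
  labels <- EBImage::bwlabel(mask)
  idx <- which(labels > 0)
  groups <- split(idx, labels[idx])
  nlab <- length(groups)
  px <- integer(nlab); py <- integer(nlab)
  for (l in seq_len(nlab)) {
    members <- groups[[l]]
    peak <- members[which.max(filtered[members])]
    py[l] <- (peak - 1L) %% nrow(filtered)       # zero-based row = y
    px[l] <- (peak - 1L) %/% nrow(filtered)      # zero-based col = x
  }
  keep <- rep(TRUE, nlab)
  if (nlab > 1) {
    d2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
    diag(d2) <- Inf
    close_pairs <- apply(d2 < params$min_separation_px^2, 1, any)
    keep <- keep & !close_pairs
  }
  h <- params$window_half_px
  inside <- px - h >= 0 & px + h < ncol(filtered) &
            py - h >= 0 & py + h < nrow(filtered)
  keep <- keep & inside
  data.frame(x = px[keep], y = py[keep], half = rep(h, sum(keep)))
}

# Pixel-integrated symmetric 2D Gaussian model evaluated on a window.
# Parameters: photons N, center (x0, y0), width sigma, offset b.
integrated_gauss_model <- function(par, xs, ys) {
  ix <- pnorm((xs - par[2] + 0.5) / par[4]) - pnorm((xs - par[2] - 0.5) / par[4])
  iy <- pnorm((ys - par[3] + 0.5) / par[4]) - pnorm((ys - par[3] - 0.5) / par[4])
  par[1] * outer(iy, ix) + par[5]
}

#' Fit a symmetric Gaussian to a raw-data window
#'
#' Unweighted least-squares fit (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) of a symmetric pixel-integrated 2-D Gaussian plus a
#' constant offset to raw (unfiltered) pixel values. The position is
#' initialized at the intensity centroid of the background-subtracted
#' window. The pixel-integrated model matches how a camera samples the PSF,
#' so noiseless windows are recovered exactly.
#'
#' @param window numeric matrix of raw pixel values.
#' @param x0,y0 zero-based pixel coordinates of the window's top-left corner
#'   in the frame (so fitted positions are reported in frame coordinates).
#' @param sigma0 initial width guess, pixels.
#' @param frame_index frame number to record, 1-based.
#' @return a one-row data frame (a `localization_fit`): `frame`, `x_px`,
#'   `y_px`, `photons`, `amplitude` (peak signal above background),
#'   `width_px`, `background`, `accepted`, `reason`.
#' @export
fit_gaussian <- function(window, x0 = 0, y0 = 0, sigma0 = 1.3, frame_index = 1L) {
  if (nrow(window) < 5 || ncol(window) < 5)
    stop("window must be at least 5x5 pixels", call. = FALSE)
  ys <- seq_len(nrow(window)) - 1
  xs <- seq_len(ncol(window)) - 1
  b0 <- min(window)
  wsub <- pmax(window - b0, 0)
  tot <- sum(wsub)
  if (tot <= 0) {
    return(localization_row(frame_index, NA, NA, NA, NA, NA, NA, FALSE, "flat"))
  }
  cx <- sum(t(wsub) * xs) / tot
  cy <- sum(wsub * ys) / tot
  start <- c(N = tot, x = cx, y = cy, s = sigma0, b = b0)
  res_fun <- function(par) as.vector(integrated_gauss_model(par, xs, ys) - window)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = res_fun,
                       lower = c(0, -1, -1, 0.2, -Inf),
                       upper = c(Inf, ncol(window), nrow(window), 10 * sigma0, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) {
    return(localization_row(frame_index, NA, NA, NA, NA, NA, NA, FALSE, "no_convergence"))
  }
  p <- fit$par
  peak <- p[1] * (pnorm(0.5 / p[4]) - pnorm(-0.5 / p[4]))^2
  inside <- p[2] >= 0 && p[2] <= ncol(window) - 1 && p[3] >= 0 && p[3] <= nrow(window) - 1
  localization_row(frame_index, x0 + p[2], y0 + p[3], p[1], peak, p[4], p[5],
                   inside && p[4] > 0, if (inside) "" else "out_of_window")
}

localization_row <- function(frame, x, y, photons, amplitude, width, background,
                             accepted, reason) {
  data.frame(frame = as.integer(frame), x_px = unname(x), y_px = unname(y),
             photons = unname(photons), amplitude = unname(amplitude),
             width_px = unname(width), background = unname(background),
             accepted = accepted, reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the basic STORM pipeline on an image stack
#'
#' Per frame: LoG filtering, thresholded segmentation, and an unweighted
#' Levenberg-Marquardt Gaussian fit on the raw data of each candidate
#' window (the filtered image is used only for detection). Fits are then
#' screened with [filter_fits()].
#'
#' @param stack an `image_stack`.
#' @param params a [detection_params()].
#' @param expected_width expected PSF standard deviation, pixels (used to
#'   initialize fits and to screen widths).
#' @param width_tolerance relative width tolerance for [filter_fits()].
#' @param amplitude_bounds amplitude acceptance interval; `NULL` uses
#'   `c(2 * noise_sd, Inf)` with the MAD noise level of the first frame.
#' @return a `localization_table` (data frame of fits with accept flags,
#'   acquisition metadata in attributes).
#' @export
run_storm <- function(stack, params, expected_width = params$log_sigma,
                      width_tolerance = 0.5, amplitude_bounds = NULL) {
  if (!inherits(stack, "image_stack")) stop("need an image_stack", call. = FALSE)
  T_ <- n_frames(stack)
  if (is.null(amplitude_bounds)) {
    amplitude_bounds <- c(2 * mad(stack$frames[, , 1]), Inf)
  }
  rows <- vector("list", T_)
  for (t in seq_len(T_)) {
    frame <- stack$frames[, , t]
    filt <- log_filter(frame, params$log_sigma)
    cand <- segment(filt, params)
    if (nrow(cand) == 0) next
    fits <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      h <- cand$half[i]
      win <- frame[(cand$y[i] - h + 1):(cand$y[i] + h + 1),
                   (cand$x[i] - h + 1):(cand$x[i] + h + 1)]
      fits[[i]] <- fit_gaussian(win, x0 = cand$x[i] - h, y0 = cand$y[i] - h,
                                sigma0 = expected_width, frame_index = t)
    }
    rows[[t]] <- do.call(rbind, fits)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) tab <- localization_row(integer(0), numeric(0), numeric(0),
                                            numeric(0), numeric(0), numeric(0),
                                            numeric(0), logical(0), character(0))
  tab <- filter_fits(tab, expected_width, width_tolerance, amplitude_bounds)
  attr(tab, "stack_dim") <- dim(stack$frames)
  attr(tab, "seed") <- stack$seed
  class(tab) <- c("localization_table", "data.frame")
  tab
}

#' Screen localization fits on width and amplitude
#'
#' Rejects fits whose width falls outside
#' `expected_width * (1 - tol, 1 + tol)` or whose amplitude falls outside
#' `amplitude_bounds`; estimates deviating strongly from their expected
#' values are overwhelmingly misfits (overlapping emitters, noise peaks).
#' The rules are order-independent and idempotent; rejection reasons are
#' recorded.
#'
#' @param table a localization table (from [run_storm()] or rbind-ed
#'   [fit_gaussian()] rows).
#' @param expected_width expected PSF standard deviation, pixels.
#' @param width_tolerance relative tolerance (default 0.5, i.e. +/- 50%).
#' @param amplitude_bounds numeric length-2 acceptance interval for the peak
#'   amplitude (default `c(0, Inf)`).
#' @return the table with updated `accepted` and `reason` columns.
#' @export
filter_fits <- function(table, expected_width, width_tolerance = 0.5,
                        amplitude_bounds = c(0, Inf)) {
  if (expected_width <= 0) stop("expected_width must be positive", call. = FALSE)
  if (nrow(table) == 0) return(table)
  ok_fit <- table$accepted & !is.na(table$width_px)
  wlo <- expected_width * (1 - width_tolerance)
  whi <- expected_width * (1 + width_tolerance)
  bad_width <- ok_fit & (table$width_px < wlo | table$width_px > whi)
  bad_amp <- ok_fit & !bad_width &
    (table$amplitude < amplitude_bounds[1] | table$amplitude > amplitude_bounds[2])
  table$accepted <- ok_fit & !bad_width & !bad_amp
  table$reason[bad_width] <- "width"
  table$reason[bad_amp] <- "amplitude"
  table$reason[table$accepted] <- ""
  table
}

#' Render a super-resolved image from accepted localizations
#'
#' A 2-D histogram of accepted localizations on an up-sampled grid,
#' optionally blurred by a small Gaussian (0.5 up-sampled pixels is a common
#' choice; the default renders the pure histogram so total mass equals the
#' number of accepted localizations).
#'
#' @param table a localization table.
#' @param dims frame dimensions `c(H, W)`; defaults to the stack dimensions
#'   recorded in the table.
#' @param upsample integer up-sampling factor.
#' @param blur_sigma Gaussian blur in up-sampled pixels (0 = none).
#' @return a `(upsample * H) x (upsample * W)` matrix.
#' @export
render_storm <- function(table, dims = NULL, upsample = 4L, blur_sigma = 0) {
  if (upsample < 1) stop("upsample must be at least 1", call. = FALSE)
  if (is.null(dims)) dims <- attr(table, "stack_dim")[1:2]
  H <- dims[1] * upsample; W <- dims[2] * upsample
  img <- matrix(0, H, W)
  acc <- table[table$accepted & !is.na(table$x_px), , drop = FALSE]
  if (nrow(acc) == 0) {
    warning("no accepted localizations to render", call. = FALSE)
    return(img)
  }
  ix <- floor((acc$x_px + 0.5) * upsample) + 1L
  iy <- floor((acc$y_px + 0.5) * upsample) + 1L
  keep <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
  for (k in which(keep)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 1
  if (blur_sigma > 0) {
    img <- EBImage::filter2(img, gaussian_kernel(blur_sigma), boundary = "replicate")
  }
  img
}

#' Match localizations to ground-truth emitters
#'
#' Greedy nearest matching of accepted localizations to true emitter
#' positions within a tolerance radius; reports recall (fraction of emitters
#' with at least one matched localization) and precision (fraction of
#' accepted localizations lying within the tolerance of some emitter).
#'
#' @param table a localization table.
#' @param emitters an [emitter_set()] (or data frame with `x`, `y`).
#' @param tol_px matching radius, pixels.
#' @return list with `recall`, `precision`, `n_locs`, `n_emitters`.
#' @export
match_localizations <- function(table, emitters, tol_px = 1) {
  acc <- table[table$accepted & !is.na(table$x_px), , drop = FALSE]
  if (nrow(acc) == 0 || nrow(emitters) == 0)
    return(list(recall = 0, precision = 0, n_locs = nrow(acc),
                n_emitters = nrow(emitters)))
  d2 <- outer(acc$x_px, emitters$x, "-")^2 + outer(acc$y_px, emitters$y, "-")^2
  nearest <- apply(d2, 1, min)
  matched_loc <- nearest <= tol_px^2
  matched_em <- apply(d2, 2, min) <= tol_px^2
  list(recall = mean(matched_em), precision = mean(matched_loc),
       n_locs = nrow(acc), n_emitters = nrow(emitters))
}
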