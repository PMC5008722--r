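#' Options for cumulant image computation
#'
#' @param order cumulant order n, 2 to 7.
#' @param time_lags scalar 0 (zero time lag, the default used in practice) or
#'   a vector of `order - 1` nonnegative frame lags.
#' @param upsample virtual-pixel factor; must divide the order so that every
#'   virtual grid node admits a pixel combination whose geometric mean falls
#'   exactly on it. Defaults to the order.
#' @param batch_frames frames per statistical block; traces are
#'   mean-subtracted per block and block cumulants averaged, which guards
#'   against slow non-stationarity such as bleaching. Default: one block for
#'   the whole stack.
#' @return an object of class `cumulant_options`.
#' @export
cumulant_options <- function(order, time_lags = 0L, upsample = order,
                             batch_frames = NULL) {
  order <- as.integer(order)
  if (order < 2 || order > 7) stop("order must be in [2, 7]", call. = FALSE)
  upsample <- as.integer(upsample)
  if (upsample < 1 || order %% upsample != 0)
    stop("upsample must be a positive divisor of the order", call. = FALSE)
  expand_lags(time_lags, order) # validates
  structure(list(order = order, time_lags = time_lags, upsample = upsample,
                 batch_frames = batch_frames),
            class = "cumulant_options")
}

#' Cumulant image container
#'
#' @param values signed numeric matrix on the up-sampled virtual grid.
#' @param order cumulant order.
#' @param stage one of `"raw"`, `"flattened"`, `"deconvolved"`,
#'   `"linearized"`.
#' @param upsample virtual-pixel factor.
#' @param psf_sigma_px PSF width (physical pixels) used for distance weights.
#' @param border_mask logical matrix marking virtual pixels with no valid
#'   pixel combination (left zero by the raw stage).
#' @param provenance free-form list (options, source-stack reference).
#' @return an object of class `cumulant_image`.
#' @export
cumulant_image <- function(values, order, stage = "raw", upsample = 1L,
                           psf_sigma_px = NULL, border_mask = NULL,
                           provenance = list()) {
  stage <- match.arg(stage, c("raw", "flattened", "deconvolved", "linearized"))
  if (stage == "linearized" && any(values < 0))
    stop("linearized images must be nonnegative", call. = FALSE)
  structure(list(values = values, order = as.integer(order), stage = stage,
                 upsample = as.integer(upsample), psf_sigma_px = psf_sigma_px,
                 border_mask = border_mask, provenance = provenance),
            class = "cumulant_image")
}

#' @export
print.cumulant_image <- function(x, ...) {
  cat(sprintf("<cumulant_image> order %d, stage %s, %d x %d (upsample %d)\n",
              x$order, x$stage, nrow(x$values), ncol(x$values), x$upsample))
  invisible(x)
}

#' Pixel combinations for the virtual grid
#'
#' For each fractional grid offset `(a/f, b/f)` the n-pixel set whose
#' geometric mean falls exactly on that virtual node, chosen to minimize the
#' sum of squared pairwise member distances (members take 0/1 pixel offsets;
#' assignment is lexicographic, so the choice is deterministic). Because the
#' member pixels are spread apart, the Gaussian PSF attenuates the
#' cross-cumulant relative to the auto-cumulant by
#' `exp(-sum_{i<j} |r_i - r_j|^2 / (2 n sigma^2))`; `distance_weight` is the
#' reciprocal correction.
#'
#' @param order cumulant order n.
#' @param psf_sigma_px PSF standard deviation in physical pixels (for the
#'   distance weight).
#' @param upsample virtual-pixel factor f; must divide n.
#' @return list with one element per offset `(a, b)`, each containing
#'   `a`, `b`, a `members` matrix (n rows of `dx`, `dy`) and
#'   `distance_weight`.
#' @export
pixel_combinations <- function(order, psf_sigma_px, upsample = order) {
  n <- as.integer(order); f <- as.integer(upsample)
  if (f < 1 || n %% f != 0)
    stop("upsample must divide the order", call. = FALSE)
  combos <- list()
  for (b in 0:(f - 1)) for (a in 0:(f - 1)) {
    sx <- n * a / f; sy <- n * b / f
    dx <- as.integer(seq_len(n) <= sx)
    dy <- as.integer(seq_len(n) <= sy)
    # sum of squared pairwise distances via n * sum((r - rbar)^2)
    s2 <- n * (sum((dx - mean(dx))^2) + sum((dy - mean(dy))^2))
    w <- exp(s2 / (2 * n * psf_sigma_px^2))
    combos[[length(combos) + 1L]] <-
      list(a = a, b = b, members = cbind(dx = dx, dy = dy),
           distance_weight = w)
  }
  combos
}

# ---- cross-cumulant image engine -------------------------------------------
#
# Members of a combination only ever take shift offsets in {0,1}^2 (plus a
# per-member time lag), so across all combinations of a given order the block
# moments E[prod X_i] reduce to a small set of "compositions": multisets of
# (dx, dy, lag) variants with multiplicities. These are computed once per
# statistical block, chunked over frames for memory, and reused by every
# combination and partition.

variant_key <- function(dx, dy, lag) paste(dx, dy, lag, sep = ",")

comp_key <- function(keys) paste(sort(keys), collapse = ";")

#' Raw n-th order cross-cumulant image
#'
#' Computes the spatio-temporal cross-cumulant of the stack on an up-sampled
#' virtual-pixel grid. Every interior virtual node receives the joint
#' cumulant of its pixel combination's member traces (see
#' [pixel_combinations()]), multiplied by the distance weight that undoes the
#' Gaussian PSF attenuation. Traces are mean-subtracted per statistical
#' block; block estimates are averaged.
#'
#' @param stack an `image_stack`.
#' @param opts a [cumulant_options()] (or an integer order).
#' @param psf_sigma_px PSF standard deviation in physical pixels; defaults to
#'   the stack's optics metadata.
#' @return a [cumulant_image()] with `stage = "raw"`. Virtual pixels on the
#'   high-index border, where no combination fits, are zero and flagged in
#'   `border_mask`.
#' @export
cross_cumulant_image <- function(stack, opts, psf_sigma_px = NULL) {
  if (!inherits(stack, "image_stack")) stop("need an image_stack", call. = FALSE)
  if (!inherits(opts, "cumulant_options")) opts <- cumulant_options(opts)
  if (is.null(psf_sigma_px)) {
    if (is.null(stack$optics)) stop("psf_sigma_px required (no optics metadata)",
                                    call. = FALSE)
    psf_sigma_px <- stack$optics$psf_sigma_px
  }
  n <- opts$order; f <- opts$upsample
  frames <- stack$frames
  H <- dim(frames)[1]; W <- dim(frames)[2]; T_ <- dim(frames)[3]
  if (T_ < 100)
    warning("fewer than 100 frames: cumulant estimates will be noisy", call. = FALSE)
  member_lags <- expand_lags(opts$time_lags, n)
  ml <- max(member_lags)
  if (T_ - ml < n + 1) stop("too few frames for the requested lags", call. = FALSE)

  combos <- pixel_combinations(n, psf_sigma_px, f)
  shifted <- f > 1
  Hi <- if (shifted) H - 1L else H
  Wi <- if (shifted) W - 1L else W
  P <- Hi * Wi

  # assemble the composition table: per combo, per partition, block comp keys
  parts <- singleton_free_partitions(n)
  combo_terms <- vector("list", length(combos))
  all_comps <- new.env(parent = emptyenv())
  for (ci in seq_along(combos)) {
    mem <- combos[[ci]]$members
    vkeys <- variant_key(mem[, "dx"], mem[, "dy"], member_lags)
    terms <- vector("list", length(parts))
    for (pi in seq_along(parts)) {
      p <- parts[[pi]]
      bkeys <- vapply(p, function(b) comp_key(vkeys[b]), character(1))
      for (bk in bkeys) if (is.null(all_comps[[bk]])) all_comps[[bk]] <- TRUE
      terms[[pi]] <- list(coef = partition_coefficient(p), blocks = bkeys)
    }
    combo_terms[[ci]] <- terms
  }
  comp_keys <- ls(all_comps)
  # decompose each composition key into variant counts
  comp_defs <- lapply(comp_keys, function(k) {
    vs <- strsplit(k, ";", fixed = TRUE)[[1]]
    tab <- table(vs)
    list(variants = names(tab), counts = as.integer(tab))
  })
  names(comp_defs) <- comp_keys
  variant_set <- unique(unlist(lapply(comp_defs, `[[`, "variants")))
  vdef <- do.call(rbind, lapply(strsplit(variant_set, ",", fixed = TRUE), as.integer))
  rownames(vdef) <- variant_set # columns: dx, dy, lag

  Tuse <- T_ - ml
  bf <- opts$batch_frames
  if (is.null(bf) || bf >= Tuse) bf <- Tuse
  batch_starts <- seq(1L, Tuse, by = bf)

  extract_variant <- function(vk, t0, len) {
    d <- vdef[vk, ]
    sub <- frames[(1 + d[2]):(Hi + d[2]), (1 + d[1]):(Wi + d[1]),
                  (t0 + d[3]):(t0 + d[3] + len - 1), drop = FALSE]
    dim(sub) <- c(P, len)
    sub
  }

  acc_img <- vector("list", length(combos))
  for (ci in seq_along(combos)) acc_img[[ci]] <- numeric(P)

  chunk_size <- max(64L, min(bf, ceiling(2e6 / P)))
  for (b0 in batch_starts) {
    blen <- min(bf, Tuse - b0 + 1L)
    if (blen < n + 1) next
    # pass 1: per-variant means over the block
    vmeans <- lapply(variant_set, function(vk) {
      s <- numeric(P); t0 <- b0
      while (t0 < b0 + blen) {
        len <- min(chunk_size, b0 + blen - t0)
        s <- s + rowSums(extract_variant(vk, t0, len))
        t0 <- t0 + len
      }
      s / blen
    })
    names(vmeans) <- variant_set
    # pass 2: accumulate composition moments
    macc <- lapply(comp_keys, function(k) numeric(P))
    names(macc) <- comp_keys
    t0 <- b0
    while (t0 < b0 + blen) {
      len <- min(chunk_size, b0 + blen - t0)
      centered <- lapply(variant_set, function(vk)
        extract_variant(vk, t0, len) - vmeans[[vk]])
      names(centered) <- variant_set
      pw <- new.env(parent = emptyenv())
      pow_of <- function(vk, p) {
        key <- paste0(vk, "^", p)
        if (is.null(pw[[key]])) pw[[key]] <- centered[[vk]]^p
        pw[[key]]
      }
      for (k in comp_keys) {
        def <- comp_defs[[k]]
        prod_m <- pow_of(def$variants[1], def$counts[1])
        if (length(def$variants) > 1) {
          for (j in 2:length(def$variants))
            prod_m <- prod_m * pow_of(def$variants[j], def$counts[j])
        }
        macc[[k]] <- macc[[k]] + rowSums(prod_m)
      }
      t0 <- t0 + len
    }
    moments <- lapply(macc, function(s) s / blen)
    # combine partitions per combination, weight by block share
    share <- blen / Tuse
    for (ci in seq_along(combos)) {
      img <- numeric(P)
      for (term in combo_terms[[ci]]) {
        v <- rep(term$coef, P)
        for (bk in term$blocks) v <- v * moments[[bk]]
        img <- img + v
      }
      acc_img[[ci]] <- acc_img[[ci]] + share * img
    }
  }

  out <- matrix(0, nrow = f * H, ncol = f * W)
  border <- matrix(TRUE, nrow = f * H, ncol = f * W)
  for (ci in seq_along(combos)) {
    a <- combos[[ci]]$a; b <- combos[[ci]]$b
    rows <- f * (seq_len(Hi) - 1L) + b + 1L
    cols <- f * (seq_len(Wi) - 1L) + a + 1L
    out[rows, cols] <- combos[[ci]]$distance_weight *
      matrix(acc_img[[ci]], nrow = Hi, ncol = Wi)
    border[rows, cols] <- FALSE
  }
  cumulant_image(out, order = n, stage = "raw", upsample = f,
                 psf_sigma_px = psf_sigma_px, border_mask = border,
                 provenance = list(options = opts, n_frames = T_,
                                   stack_seed = stack$seed))
}

#' Flatten a raw cumulant image
#'
#' Virtual pixels built from different pixel combinations carry residual
#' brightness differences (e.g. when the PSF width used for the distance
#' weights is misestimated), visible as a periodic checkerboard. Flattening
#' rescales each of the `upsample^2` interleaved sub-grids so its mean
#' absolute value matches the cross-subgrid average. Gains are positive, so
#' no sign changes are introduced; an all-zero image is returned unchanged.
#'
#' @param ci a raw [cumulant_image()].
#' @return a [cumulant_image()] with `stage = "flattened"`.
#' @export
flatten <- function(ci) {
  stopifnot(inherits(ci, "cumulant_image"))
  if (ci$stage != "raw") stop("flatten expects a raw cumulant image", call. = FALSE)
  v <- ci$values; f <- ci$upsample
  valid <- if (is.null(ci$border_mask)) matrix(TRUE, nrow(v), ncol(v)) else !ci$border_mask
  if (all(v[valid] == 0) || f == 1) {
    out <- ci; out$stage <- "flattened"; return(out)
  }
  sub_r <- (row(v) - 1L) %% f
  sub_c <- (col(v) - 1L) %% f
  target <- mean(abs(v[valid]))
  for (b in 0:(f - 1)) for (a in 0:(f - 1)) {
    m <- valid & sub_r == b & sub_c == a
    mu <- mean(abs(v[m]))
    if (mu > 0) v[m] <- v[m] * (target / mu)
  }
  cumulant_image(v, ci$order, "flattened", ci$upsample, ci$psf_sigma_px,
                 ci$border_mask, ci$provenance)
}

gaussian_kernel <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(2L, ceiling(3 * sigma))
  x <- (-radius):radius
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

#' Richardson-Lucy deconvolution of a cumulant image
#'
#' The order-n cumulant image is blurred by the n-th power of the PSF, a
#' Gaussian of width `sigma / sqrt(n)` (in physical pixels, i.e.
#' `sigma * upsample / sqrt(n)` on the virtual grid). A fixed number of
#' multiplicative Richardson-Lucy iterations with that kernel sharpens the
#' image towards the full n-fold resolution gain; too many iterations cause
#' the usual ringing artifacts, so the count is exposed. Negative values
#' (possible in raw/flattened cumulants) are clipped to zero on entry, as
#' required by the multiplicative update.
#'
#' @param ci a flattened [cumulant_image()].
#' @param iterations number of RL iterations (default 10).
#' @param psf_sigma_px PSF width in physical pixels; defaults to the value
#'   recorded in the image.
#' @return a [cumulant_image()] with `stage = "deconvolved"`.
#' @export
deconvolve <- function(ci, iterations = 10, psf_sigma_px = NULL) {
  stopifnot(inherits(ci, "cumulant_image"))
  if (iterations < 1) stop("iterations must be positive", call. = FALSE)
  if (is.null(psf_sigma_px)) psf_sigma_px <- ci$psf_sigma_px
  if (is.null(psf_sigma_px)) stop("psf_sigma_px required", call. = FALSE)
  sigma_v <- psf_sigma_px * ci$upsample / sqrt(ci$order)
  radius <- min(max(2L, ceiling(3 * sigma_v)),
                floor((min(dim(ci$values)) - 1) / 2))
  k <- gaussian_kernel(sigma_v, radius)
  d <- pmax(ci$values, 0)
  eps <- 1e-12 * max(d, 1e-300)
  est <- d + eps
  for (it in seq_len(iterations)) {
    conv <- EBImage::filter2(est, k, boundary = "replicate")
    ratio <- d / pmax(conv, eps)
    est <- est * EBImage::filter2(ratio, k, boundary = "replicate")
  }
  cumulant_image(est, ci$order, "deconvolved", ci$upsample, psf_sigma_px,
                 ci$border_mask, ci$provenance)
}

#' Linearize the brightness response of a cumulant image
#'
#' An order-n cumulant responds to emitter brightness as the n-th power,
#' so bright emitters dominate dim ones nonlinearly. The balanced-SOFI
#' linearization takes the pixelwise n-th root of the magnitude,
#' `|value|^(1/n)`, restoring a linear brightness scale. Zeros map to zeros;
#' the output is nonnegative.
#'
#' @param ci a deconvolved (or flattened) [cumulant_image()].
#' @return a [cumulant_image()] with `stage = "linearized"`.
#' @export
linearize <- function(ci) {
  stopifnot(inherits(ci, "cumulant_image"))
  v <- abs(ci$values)^(1 / ci$order)
  cumulant_image(v, ci$order, "linearized", ci$upsample, ci$psf_sigma_px,
                 ci$border_mask, ci$provenance)
}

#' Balanced SOFI pipeline over several cumulant orders
#'
#' Runs raw cross-cumulant, flattening, Richardson-Lucy deconvolution and
#' brightness linearization for each requested order, and also returns the
#' widefield (temporal mean) image as the diffraction-limited reference.
#'
#' @param stack an `image_stack`.
#' @param orders integer vector of cumulant orders within 2..7.
#' @param psf_sigma_px PSF standard deviation in physical pixels; defaults to
#'   the stack's optics metadata.
#' @param iterations Richardson-Lucy iteration count.
#' @param time_lags,batch_frames passed to [cumulant_options()].
#' @param keep_stages if `TRUE`, all intermediate stages are returned per
#'   order; otherwise only the linearized image.
#' @return list with `widefield` (matrix) and `orders` (named list, one entry
#'   per order).
#' @export
bsofi_pipeline <- function(stack, orders = 2:7, psf_sigma_px = NULL,
                           iterations = 10, time_lags = 0L,
                           batch_frames = NULL, keep_stages = FALSE) {
  if (!inherits(stack, "image_stack")) stop("need an image_stack", call. = FALSE)
  if (n_frames(stack) < 2) stop("stack must contain at least 2 frames", call. = FALSE)
  if (!all(orders %in% 2:7)) stop("orders must lie in [2, 7]", call. = FALSE)
  res <- list()
  for (n in orders) {
    opts <- cumulant_options(n, time_lags = time_lags, batch_frames = batch_frames)
    raw <- cross_cumulant_image(stack, opts, psf_sigma_px)
    flat <- flatten(raw)
    dec <- deconvolve(flat, iterations = iterations)
    lin <- linearize(dec)
    res[[paste0("order", n)]] <-
      if (keep_stages) list(raw = raw, flattened = flat, deconvolved = dec,
                            linearized = lin) else lin
  }
  list(widefield = widefield_image(stack), orders = res)
}
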