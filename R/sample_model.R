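#' Field of view of the camera
#'
#' Describes the pixel grid onto which emitters are imaged. Continuous
#' positions are expressed in pixel units with the origin at the center of
#' pixel (0, 0); pixel (i, j) covers the square `[i - 1/2, i + 1/2] x
#' [j - 1/2, j + 1/2]`. Integer pixel indices are zero-based.
#'
#' @param width_px,height_px integer pixel counts (at least 8).
#' @param pixel_size_nm physical size of one camera pixel at the sample
#'   plane, nanometers.
#' @return an object of class `field_of_view`.
#' @export
field_of_view <- function(width_px, height_px, pixel_size_nm) {
  if (width_px < 8 || height_px < 8)
    stop("field of view must be at least 8x8 pixels", call. = FALSE)
  if (pixel_size_nm <= 0)
    stop("pixel_size_nm must be positive", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_nm = pixel_size_nm),
            class = "field_of_view")
}

#' @export
print.field_of_view <- function(x, ...) {
  cat(sprintf("<field_of_view> %d x %d px, %.1f nm/px (%.2f x %.2f um)\n",
              x$width_px, x$height_px, x$pixel_size_nm,
              x$width_px * x$pixel_size_nm / 1e3,
              x$height_px * x$pixel_size_nm / 1e3))
  invisible(x)
}

fov_area_um2 <- function(fov) {
  (fov$width_px * fov$pixel_size_nm / 1e3) * (fov$height_px * fov$pixel_size_nm / 1e3)
}

#' Set of fluorescent emitters
#'
#' Holds continuous emitter positions (pixel units, see [field_of_view()])
#' and per-emitter brightness, i.e. the expected number of detected photons
#' per frame while the emitter is fully in the on state.
#'
#' @param x,y numeric vectors of positions in pixel units.
#' @param brightness expected detected photons per fully-on frame; scalar or
#'   per-emitter vector.
#' @param fov the [field_of_view()] the positions refer to.
#' @return an object of class `emitter_set` (a data frame with columns
#'   `x`, `y`, `brightness` plus the field of view as an attribute).
#' @export
emitter_set <- function(x, y, brightness, fov) {
  stopifnot(length(x) == length(y))
  brightness <- rep_len(brightness, length(x))
  if (length(x) > 0 && any(brightness <= 0))
    stop("brightness must be positive", call. = FALSE)
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    brightness = as.numeric(brightness))
  attr(out, "fov") <- fov
  class(out) <- c("emitter_set", "data.frame")
  out
}

#' @export
print.emitter_set <- function(x, ...) {
  fov <- attr(x, "fov")
  cat(sprintf("<emitter_set> %d emitters on %d x %d px FOV\n",
              nrow(x), fov$width_px, fov$height_px))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Spatial pattern specification for emitter placement
#'
#' @param kind one of `"uniform_random"`, `"points"`, `"filament"`.
#' @param density emitters per square micrometer (`uniform_random`) or per
#'   micrometer of curve length (`filament`). Ignored for `points`.
#' @param geometry for `points`: a 2-column matrix/data frame of (x, y) pixel
#'   positions. For `filament`: a 2-column matrix of control points (pixel
#'   units) of a piecewise-linear curve. For `uniform_random`: optionally a
#'   bounding box `c(x0, y0, x1, y1)` in pixel units restricting placement
#'   (defaults to the whole field of view).
#' @param jitter_sigma_px isotropic Gaussian jitter applied to filament
#'   emitters, pixels. Default 0 (on-curve).
#' @param fixed_count if not `NULL`, place exactly this many emitters instead
#'   of drawing the count from the Poisson law (reproducible worked examples).
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(kind = c("uniform_random", "points", "filament"),
                         density = NULL, geometry = NULL,
                         jitter_sigma_px = 0, fixed_count = NULL) {
  kind <- match.arg(kind)
  if (kind != "points") {
    if (is.null(density) || density <= 0)
      stop("density must be positive for generated patterns", call. = FALSE)
  }
  if (kind %in% c("points", "filament")) {
    if (is.null(geometry)) stop("geometry is required for kind = ", kind, call. = FALSE)
    geometry <- as.matrix(geometry)
    if (ncol(geometry) != 2) stop("geometry must have two columns (x, y)", call. = FALSE)
  }
  structure(list(kind = kind, density = density, geometry = geometry,
                 jitter_sigma_px = jitter_sigma_px, fixed_count = fixed_count),
            class = "pattern_spec")
}

#' Generate uniformly random emitters at a given areal density
#'
#' The emitter count is drawn from a Poisson law with mean
#' `density * area`, matching random labeling; positions are i.i.d. uniform
#' over the field of view. Identical seeds give identical output.
#'
#' @param fov a [field_of_view()].
#' @param density_per_um2 emitters per square micrometer.
#' @param brightness expected detected photons per fully-on frame.
#' @param seed integer seed.
#' @param fixed_count if not `NULL`, place exactly this many emitters.
#' @param region optional bounding box `c(x0, y0, x1, y1)` in pixel units.
#' @return an [emitter_set()].
#' @export
#' @examples
#' fov <- field_of_view(16, 16, 100)
#' generate_random_emitters(fov, density_per_um2 = 10, brightness = 500, seed = 1)
generate_random_emitters <- function(fov, density_per_um2, brightness, seed,
                                     fixed_count = NULL, region = NULL) {
  if (!inherits(fov, "field_of_view")) stop("fov must be a field_of_view", call. = FALSE)
  if (density_per_um2 <= 0) stop("density must be positive", call. = FALSE)
  if (is.null(region)) {
    region <- c(-0.5, -0.5, fov$width_px - 0.5, fov$height_px - 0.5)
  }
  w_um <- (region[3] - region[1]) * fov$pixel_size_nm / 1e3
  h_um <- (region[4] - region[2]) * fov$pixel_size_nm / 1e3
  if (w_um <= 0 || h_um <= 0) stop("degenerate placement region", call. = FALSE)
  mean_count <- density_per_um2 * w_um * h_um
  with_stream_seed(seed, "sample", {
    n <- if (is.null(fixed_count)) rpois(1, mean_count) else as.integer(fixed_count)
    x <- runif(n, region[1], region[3])
    y <- runif(n, region[2], region[4])
    emitter_set(x, y, brightness, fov)
  })
}

#' Generate emitters along a structured pattern
#'
#' `points` patterns return exactly the listed positions. `filament` patterns
#' place emitters along a piecewise-linear curve with exponential arc-length
#' gaps of mean `1/density` (a Poisson process on the curve), optionally
#' jittered isotropically. `uniform_random` delegates to
#' [generate_random_emitters()].
#'
#' @param fov a [field_of_view()].
#' @param spec a [pattern_spec()].
#' @param brightness expected detected photons per fully-on frame.
#' @param seed integer seed (unused for `points`).
#' @return an [emitter_set()].
#' @export
generate_pattern_emitters <- function(fov, spec, brightness, seed = 0L) {
  if (!inherits(spec, "pattern_spec")) stop("spec must be a pattern_spec", call. = FALSE)
  switch(spec$kind,
    points = emitter_set(spec$geometry[, 1], spec$geometry[, 2], brightness, fov),
    uniform_random = {
      region <- if (!is.null(spec$geometry)) as.numeric(spec$geometry) else NULL
      generate_random_emitters(fov, spec$density, brightness, seed,
                               fixed_count = spec$fixed_count, region = region)
    },
    filament = {
      cp <- spec$geometry
      seg <- diff(cp)
      seg_len_px <- sqrt(rowSums(seg^2))
      cum_px <- c(0, cumsum(seg_len_px))
      total_um <- cum_px[length(cum_px)] * fov$pixel_size_nm / 1e3
      if (total_um <= 0) stop("filament has zero length", call. = FALSE)
      with_stream_seed(seed, "sample", {
        n <- if (is.null(spec$fixed_count)) rpois(1, spec$density * total_um)
             else as.integer(spec$fixed_count)
        # Poisson process on the curve <=> n uniform arc-length positions
        s_um <- sort(runif(n, 0, total_um))
        s_px <- s_um * 1e3 / fov$pixel_size_nm
        idx <- findInterval(s_px, cum_px, rightmost.closed = TRUE)
        idx <- pmin(idx, nrow(seg))
        frac <- (s_px - cum_px[idx]) / seg_len_px[idx]
        x <- cp[idx, 1] + frac * seg[idx, 1]
        y <- cp[idx, 2] + frac * seg[idx, 2]
        if (spec$jitter_sigma_px > 0) {
          x <- x + rnorm(n, 0, spec$jitter_sigma_px)
          y <- y + rnorm(n, 0, spec$jitter_sigma_px)
        }
        emitter_set(x, y, brightness, fov)
      })
    },
    stop("unknown pattern kind: ", spec$kind, call. = FALSE)
  )
}

#' Write / read an emitter set as a 3-column CSV
#'
#' The CSV (columns `x_px`, `y_px`, `brightness`) serves as ground truth for
#' localization benchmarking and as an exchange format for user-supplied
#' patterns.
#'
#' @param emitters an [emitter_set()].
#' @param path file path.
#' @export
write_emitters <- function(emitters, path) {
  df <- data.frame(x_px = emitters$x, y_px = emitters$y,
                   brightness = emitters$brightness)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emitters
#' @param fov the [field_of_view()] the positions refer to.
#' @export
read_emitters <- function(path, fov) {
  df <- read.csv(path)
  emitter_set(df$x_px, df$y_px, df$brightness, fov)
}
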