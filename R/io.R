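#' Write an image stack as a multi-page TIFF
#'
#' Two modes: `bits = 16` stores rounded integer digital units (bit-exact
#' round trip for integer-valued data in `[0, 65535]`); `bits = 32` stores
#' 32-bit samples normalized by a power-of-two scale factor recorded in a
#' YAML sidecar (`<path>.yaml`), giving a relative round-trip precision of
#' `2^-32` of the full scale (the TIFF backend quantizes 32-bit samples on a
#' fixed-point grid). The sidecar also carries pixel size, units and the
#' generating seed.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @param bits 16 (unsigned integer) or 32 (float).
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  fr <- stack$frames
  T_ <- dim(fr)[3]
  if (bits == 16) {
    v <- round(fr)
    if (any(v < 0) || any(v > 65535))
      stop("16-bit mode requires values in [0, 65535]", call. = FALSE)
    pages <- lapply(seq_len(T_), function(t) v[, , t] / 65535)
    scale <- 65535
  } else if (bits == 32) {
    mx <- max(abs(fr), 1e-300)
    scale <- 2^ceiling(log2(mx))
    if (any(fr < 0)) stop("float mode stores nonnegative stacks", call. = FALSE)
    pages <- lapply(seq_len(T_), function(t) fr[, , t] / scale)
  } else stop("bits must be 16 or 32", call. = FALSE)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                                   compression = "none", reduce = FALSE))
  meta <- list(bits = bits, scale = scale, units = stack$units,
               seed = stack$seed,
               pixel_size_nm = if (!is.null(stack$fov)) stack$fov$pixel_size_nm else NULL,
               psf_sigma_px = if (!is.null(stack$optics)) stack$optics$psf_sigma_px else NULL)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' Restores the scaling recorded in the YAML sidecar written by
#' [write_stack()]; a plain externally produced TIFF (no sidecar) is read
#' as-is, which allows analysis-only use on acquired data.
#'
#' @param path TIFF file path.
#' @return an `image_stack`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (!is.null(meta)) {
    arr <- if (meta$bits == 16) round(arr * meta$scale) else arr * meta$scale
  }
  fov <- NULL
  if (!is.null(meta$pixel_size_nm) && all(dim(arr)[1:2] >= 8))
    fov <- field_of_view(dim(arr)[2], dim(arr)[1], meta$pixel_size_nm)
  optics <- NULL
  if (!is.null(meta$psf_sigma_px))
    optics <- optics_config(psf_sigma_px = meta$psf_sigma_px)
  image_stack(arr, fov = fov, optics = optics,
              units = if (!is.null(meta)) meta$units else "du",
              seed = meta$seed)
}

#' Write / read a localization table as CSV
#'
#' Column layout (`frame, x_px, y_px, photons, amplitude, width_px,
#' background, accepted, reason`) follows common single-molecule table
#' conventions.
#'
#' @param table a localization table.
#' @param path file path.
#' @export
write_localizations <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$reason[is.na(tab$reason)] <- ""
  class(tab) <- c("localization_table", "data.frame")
  tab
}

# ---- run configuration ------------------------------------------------------

config_schema <- list(
  fov = c("width_px", "height_px", "pixel_size_nm"),
  sample = c("pattern", "density", "geometry", "brightness", "jitter_sigma_px",
             "fixed_count", "region"),
  photophysics = c("tau_on", "tau_off", "t_bleach", "initial_on_prob"),
  optics = c("numerical_aperture", "emission_wavelength_nm", "psf_sigma_px"),
  camera = c("quantum_efficiency", "gain", "dark_noise_sd", "baseline",
             "frame_time_s", "em_gain", "quantize"),
  acquisition = c("n_frames", "background"),
  sofi = c("orders", "iterations", "time_lags", "batch_frames"),
  storm = c("detection_threshold", "width_tolerance", "min_separation_px",
            "upsample"),
  seed = NULL,
  name = NULL
)

#' Validate a nested run configuration
#'
#' Checks that only known sections and keys are present and that required
#' sections exist; unknown keys are rejected with a message naming them.
#'
#' @param config nested list (as parsed from YAML).
#' @return the validated config, invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  unknown_sections <- setdiff(names(config), names(config_schema))
  if (length(unknown_sections))
    stop("unknown config section(s): ", paste(unknown_sections, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    unknown <- setdiff(names(config[[sec]]), allowed)
    if (length(unknown))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  required <- c("fov", "sample", "photophysics", "camera", "acquisition")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  class(config) <- c("run_config", "list")
  invisible(config)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a `run_config` (or plain nested list).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(config) {
  cf <- config
  fov <- field_of_view(cf$fov$width_px, cf$fov$height_px, cf$fov$pixel_size_nm)
  oc <- cf$optics
  optics <- optics_config(
    numerical_aperture = oc$numerical_aperture %||% 1.2,
    emission_wavelength_nm = oc$emission_wavelength_nm %||% 520,
    pixel_size_nm = cf$fov$pixel_size_nm,
    psf_sigma_px = oc$psf_sigma_px)
  cm <- cf$camera
  camera <- camera_config(
    quantum_efficiency = cm$quantum_efficiency %||% 0.9,
    gain = cm$gain %||% 1, dark_noise_sd = cm$dark_noise_sd %||% 1,
    baseline = cm$baseline %||% 100, frame_time_s = cm$frame_time_s %||% 0.01,
    em_gain = cm$em_gain %||% TRUE, quantize = cm$quantize %||% FALSE)
  pp <- cf$photophysics
  photo <- photophysics_params(pp$tau_on, pp$tau_off,
                               t_bleach = pp$t_bleach %||% Inf,
                               initial_on_prob = pp$initial_on_prob)
  sm <- cf$sample
  geometry <- sm$geometry
  if (!is.null(geometry)) geometry <- do.call(rbind, lapply(geometry, unlist))
  if (!is.null(sm$region)) geometry <- unlist(sm$region) # c(x0, y0, x1, y1)
  pattern <- pattern_spec(sm$pattern %||% "uniform_random",
                          density = sm$density, geometry = geometry,
                          jitter_sigma_px = sm$jitter_sigma_px %||% 0,
                          fixed_count = sm$fixed_count)
  list(fov = fov, optics = optics, camera = camera, photophysics = photo,
       pattern = pattern, brightness = sm$brightness %||% 500,
       n_frames = cf$acquisition$n_frames,
       background = cf$acquisition$background %||% 0,
       seed = cf$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a stack from a run configuration
#'
#' @param config a `run_config` (from [read_config()] or [load_preset()]).
#' @param seed overrides the config seed if given.
#' @return an `image_stack`.
#' @export
simulate_from_config <- function(config, seed = NULL) {
  ob <- config_objects(config)
  simulate_stack(pattern = ob$pattern, brightness = ob$brightness,
                 photophysics = ob$photophysics, fov = ob$fov,
                 optics = ob$optics, camera = ob$camera,
                 n_frames = ob$n_frames, background = ob$background,
                 seed = seed %||% ob$seed)
}

#' List and load bundled scenario presets
#'
#' Ships configuration files for five representative acquisition scenarios:
#' `standard` (conditions under which single-molecule localization resolves
#' individual emitters), `short_acquisition` (600 frames),
#' `short_off_state` (off-state lifetime on the order of the frame time),
#' `low_snr` (few photons per switching event, around 8 dB), and
#' `high_density` (1000 emitters per square micrometer). Every parameter is
#' recorded in the file.
#'
#' @return `list_presets()`: character vector of preset names.
#' @export
list_presets <- function() {
  sub("\\.yaml$", "", dir(system.file("presets", package = "sofisim"),
                          pattern = "\\.yaml$"))
}

#' @rdname list_presets
#' @param name preset name (see [list_presets()]).
#' @export
load_preset <- function(name) {
  path <- system.file("presets", paste0(name, ".yaml"), package = "sofisim")
  if (path == "") stop("unknown preset: ", name, call. = FALSE)
  read_config(path)
}

#' Simulate, analyze and report in one call
#'
#' Simulates a stack from the configuration, computes the widefield image,
#' balanced-SOFI images for the configured orders, the STORM localization
#' table and rendering, and quality metrics; writes everything (TIFFs,
#' CSVs and a side-by-side PNG panel) to `out_dir`. Deterministic given the
#' seed: rerunning yields byte-identical tables.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed.
#' @return list with `stack`, `widefield`, `sofi`, `storm`, `metrics`
#'   (invisibly).
#' @export
run_compare <- function(config, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% (config$seed %||% 1L)
  stack <- simulate_from_config(config, seed = seed)
  orders <- unlist(config$sofi$orders) %||% 2:7
  sofi <- bsofi_pipeline(stack, orders = orders,
                         iterations = config$sofi$iterations %||% 10,
                         batch_frames = config$sofi$batch_frames)
  sp <- config$storm
  dp <- detection_params(log_sigma = stack$optics$psf_sigma_px,
                         detection_threshold = sp$detection_threshold %||% 5,
                         min_separation_px = sp$min_separation_px)
  locs <- run_storm(stack, dp, width_tolerance = sp$width_tolerance %||% 0.5)
  storm_img <- suppressWarnings(
    render_storm(locs, upsample = sp$upsample %||% 4L))
  qm <- estimate_snr_sb(stack)
  gt <- stack$ground_truth
  metrics <- data.frame(
    metric = c("snr_db", "s_over_b", "i_peak", "on_time_ratio_truth",
               "n_emitters", "n_localizations", "n_accepted"),
    value = c(qm$snr_db, qm$s_over_b, qm$i_peak,
              estimate_on_time_ratio(gt$traces),
              nrow(gt$emitters), nrow(locs), sum(locs$accepted)))
  # outputs (16-bit camera convention; dense samples can exceed that range)
  stack_bits <- if (max(stack$frames) <= 65535) 16 else 32
  write_stack(stack, file.path(out_dir, "stack.tif"), bits = stack_bits)
  wf <- stack; wf$frames <- array(sofi$widefield, dim = c(dim(sofi$widefield), 1))
  write_stack(wf, file.path(out_dir, "widefield.tif"), bits = 32)
  for (nm in names(sofi$orders)) {
    ci <- sofi$orders[[nm]]
    si <- image_stack(ci$values, units = "cumulant")
    write_stack(si, file.path(out_dir, paste0("sofi_", nm, ".tif")), bits = 32)
  }
  write_localizations(locs, file.path(out_dir, "storm.csv"))
  write_stack(image_stack(storm_img, units = "counts"),
              file.path(out_dir, "storm.tif"), bits = 32)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write_panel_png(file.path(out_dir, "panel.png"), sofi, storm_img)
  invisible(list(stack = stack, widefield = sofi$widefield, sofi = sofi,
                 storm = list(table = locs, image = storm_img),
                 metrics = metrics))
}

write_panel_png <- function(path, sofi, storm_img) {
  imgs <- c(list(widefield = sofi$widefield),
            lapply(sofi$orders, function(ci) ci$values),
            list(storm = storm_img))
  n <- length(imgs)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  png(path, width = 280 * nc, height = 280 * nr)
  par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
  for (nm in names(imgs)) {
    m <- imgs[[nm]]
    image(t(m)[, nrow(m):1], col = gray.colors(256), axes = FALSE)
    title(nm)
  }
  dev.off()
  invisible(path)
}
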