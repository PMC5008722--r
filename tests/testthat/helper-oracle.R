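# Independent brute-force oracles used across the suite. Kept deliberately
# separate from the package implementation: partitions are enumerated by a
# different (recursive, full, singleton-including) scheme and moments are
# taken of the raw (uncentered) series.

oracle_all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- oracle_all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# joint cumulant from raw moments over ALL set partitions
oracle_joint_cumulant <- function(xs) {
  n <- length(xs)
  acc <- 0
  for (p in oracle_all_partitions(n)) {
    term <- (-1)^(length(p) - 1) * factorial(length(p) - 1)
    for (b in p) {
      pr <- xs[[b[1]]]
      for (i in b[-1]) pr <- pr * xs[[i]]
      term <- term * mean(pr)
    }
    acc <- acc + term
  }
  acc
}

# population n-th cumulant of a Bernoulli(p) variable from its raw moments
# (all equal to p) via the same full-partition expansion
oracle_bernoulli_cumulant <- function(n, p) {
  acc <- 0
  for (part in oracle_all_partitions(n)) {
    acc <- acc + (-1)^(length(part) - 1) * factorial(length(part) - 1) *
      p^length(part)
  }
  acc
}

# standard small simulation shared by several tests: one isolated emitter,
# quiet unit-gain camera
make_single_emitter_stack <- function(n_frames, sigma = 1.3, brightness = 1000,
                                      fov_px = 16, seed = 5, background = 2,
                                      x = NULL, y = NULL) {
  fov <- field_of_view(fov_px, fov_px, 100)
  c0 <- (fov_px - 1) / 2
  em <- emitter_set(x %||% c0, y %||% c0, brightness, fov)
  simulate_stack(
    emitters = em,
    photophysics = photophysics_params(0.02, 0.2),
    fov = fov,
    optics = optics_config(psf_sigma_px = sigma, pixel_size_nm = 100),
    camera = camera_config(quantum_efficiency = 0.9, gain = 1,
                           dark_noise_sd = 1, baseline = 100,
                           frame_time_s = 0.01, em_gain = FALSE),
    n_frames = n_frames, background = background, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
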