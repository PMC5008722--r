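#' Photophysical parameters of a blinking fluorophore
#'
#' Two-state (on/off) continuous-time Markov model with exponentially
#' distributed dwell times plus an exponential photobleaching clock.
#'
#' @param tau_on mean on-state lifetime, seconds.
#' @param tau_off mean off-state lifetime, seconds.
#' @param t_bleach mean time before permanent bleaching, seconds; `Inf`
#'   disables bleaching. The bleaching clock runs in wall time from t = 0:
#'   under the constant illumination typical of fluctuation imaging,
#'   switching and excitation are proportional, so a wall-time exponential
#'   clock reproduces the exponential fade of the average fluorescence.
#' @param initial_on_prob probability that an emitter starts in the on state.
#'   `NULL` (default) draws the initial state from the stationary
#'   distribution `tau_on / (tau_on + tau_off)` so there is no equilibration
#'   transient.
#' @return an object of class `photophysics_params`.
#' @export
#' @examples
#' photophysics_params(tau_on = 0.01, tau_off = 0.1)
photophysics_params <- function(tau_on, tau_off, t_bleach = Inf,
                                initial_on_prob = NULL) {
  if (tau_on <= 0 || tau_off <= 0) stop("lifetimes must be positive", call. = FALSE)
  if (t_bleach <= 0) stop("t_bleach must be positive (Inf allowed)", call. = FALSE)
  if (is.null(initial_on_prob)) initial_on_prob <- tau_on / (tau_on + tau_off)
  if (initial_on_prob < 0 || initial_on_prob > 1)
    stop("initial_on_prob must be in [0, 1]", call. = FALSE)
  structure(list(tau_on = tau_on, tau_off = tau_off, t_bleach = t_bleach,
                 initial_on_prob = initial_on_prob),
            class = "photophysics_params")
}

#' On-time ratio of a two-state blinking model
#'
#' The duty parameter `rho_on = tau_on / tau_off`. Reversibly photoswitchable
#' fluorescent proteins typically have on-time ratios around 0.1; organic
#' dyes much smaller (below 0.01).
#'
#' @param params a [photophysics_params()].
#' @return `tau_on / tau_off`.
#' @export
on_time_ratio <- function(params) {
  params$tau_on / params$tau_off
}

#' Average blinking rate
#'
#' The rate of full on/off cycles, `1 / (tau_on + tau_off)` per second.
#'
#' @param params a [photophysics_params()].
#' @return rate in 1/s.
#' @export
blinking_rate <- function(params) {
  1 / (params$tau_on + params$tau_off)
}

# Sample alternating exponential dwell intervals until `t_end`, starting in
# `state0` (TRUE = on). Returns start times, durations and states. Dwells are
# drawn in even-sized chunks so the alternation bookkeeping stays simple.
sample_dwell_intervals <- function(params, t_end, state0) {
  rate_cycle <- 2 / (params$tau_on + params$tau_off)
  starts <- numeric(0); durs <- numeric(0); states <- logical(0)
  t <- 0; s <- state0
  while (t < t_end) {
    half <- max(8L, ceiling((t_end - t) * rate_cycle))
    chunk <- 2L * half
    first <- seq(1L, chunk, 2L); second <- seq(2L, chunk, 2L)
    d <- numeric(chunk)
    if (s) {
      d[first] <- rexp(half, 1 / params$tau_on)
      d[second] <- rexp(half, 1 / params$tau_off)
    } else {
      d[first] <- rexp(half, 1 / params$tau_off)
      d[second] <- rexp(half, 1 / params$tau_on)
    }
    st <- t + cumsum(c(0, d[-chunk]))
    starts <- c(starts, st); durs <- c(durs, d)
    states <- c(states, rep(c(s, !s), half))
    t <- st[chunk] + d[chunk]
    # chunk is even, so the next interval starts again in state `s`
  }
  keep <- starts < t_end
  list(start = starts[keep], dur = durs[keep], state = states[keep])
}

#' Simulate a frame-integrated blinking trace for one emitter
#'
#' Samples exponential on/off dwell times in continuous time, then integrates
#' the on-time within each exposure window into an emissive fraction in
#' `[0, 1]` (partial-frame blinking produces fractional brightness). An
#' exponential bleaching clock (mean `t_bleach`, wall time) truncates the
#' trace; frames at or beyond `bleach_frame` are exactly 0.
#'
#' @param params a [photophysics_params()].
#' @param frame_time_s exposure time per frame, seconds.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param binary_sampling if `TRUE`, sample the on/off state at mid-exposure
#'   instead of integrating (emissive fraction is then 0 or 1).
#' @return an object of class `state_trace` with elements
#'   `emissive_fraction` (length `n_frames`), `bleach_frame` (zero-based
#'   index of the first fully dark frame, or `NA`), and `dwells` (list with
#'   completed `on` and `off` dwell durations, for diagnostics).
#' @export
#' @examples
#' p <- photophysics_params(0.01, 0.1)
#' tr <- simulate_state_trace(p, frame_time_s = 0.01, n_frames = 100, seed = 1)
#' mean(tr$emissive_fraction)
simulate_state_trace <- function(params, frame_time_s, n_frames, seed,
                                 binary_sampling = FALSE) {
  if (frame_time_s <= 0) stop("frame_time_s must be positive", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be positive", call. = FALSE)
  with_stream_seed(seed, "photophysics",
    simulate_state_trace_impl(params, frame_time_s, n_frames, binary_sampling))
}

simulate_state_trace_impl <- function(params, frame_time_s, n_frames,
                                      binary_sampling = FALSE) {
  t_total <- frame_time_s * n_frames
  t_bleach <- if (is.finite(params$t_bleach)) rexp(1, 1 / params$t_bleach) else Inf
  t_end <- min(t_total, t_bleach)
  state0 <- runif(1) < params$initial_on_prob
  frac <- numeric(n_frames)
  bleach_frame <- if (t_bleach < t_total) min(n_frames, floor(t_bleach / frame_time_s) + 1) else NA_integer_
  if (t_end <= 0) {
    return(structure(list(emissive_fraction = frac, bleach_frame = 0L,
                          dwells = list(on = numeric(0), off = numeric(0))),
                     class = "state_trace"))
  }
  iv <- sample_dwell_intervals(params, t_end, state0)
  on_i <- which(iv$state)
  if (binary_sampling) {
    mid <- (seq_len(n_frames) - 0.5) * frame_time_s
    live <- mid < t_end
    if (any(live)) {
      idx <- findInterval(mid[live], iv$start)
      frac[live] <- as.numeric(iv$state[pmax(idx, 1L)])
    }
  } else if (length(on_i)) {
    s <- iv$start[on_i]
    e <- pmin(iv$start[on_i] + iv$dur[on_i], t_end)
    s <- pmin(s, t_end)
    for (k in seq_along(s)) {
      if (e[k] <= s[k]) next
      f0 <- floor(s[k] / frame_time_s)
      f1 <- min(floor((e[k] - 1e-12) / frame_time_s), n_frames - 1)
      if (f0 > n_frames - 1) next
      if (f0 == f1) {
        frac[f0 + 1] <- frac[f0 + 1] + (e[k] - s[k]) / frame_time_s
      } else {
        frac[f0 + 1] <- frac[f0 + 1] + ((f0 + 1) * frame_time_s - s[k]) / frame_time_s
        frac[f1 + 1] <- frac[f1 + 1] + (e[k] - f1 * frame_time_s) / frame_time_s
        if (f1 > f0 + 1) frac[(f0 + 2):f1] <- frac[(f0 + 2):f1] + 1
      }
    }
  }
  frac <- pmin(pmax(frac, 0), 1)
  # completed dwells only (exclude the interval cut by t_end) for KS checks
  completed <- iv$start + iv$dur <= t_end
  structure(list(emissive_fraction = frac,
                 bleach_frame = bleach_frame,
                 dwells = list(on = iv$dur[iv$state & completed],
                               off = iv$dur[!iv$state & completed])),
            class = "state_trace")
}

#' Simulate blinking traces for a set of emitters
#'
#' All emitters share the same photophysical parameters (sample-wide
#' heterogeneity is deliberately not modelled); each emitter gets an
#' independent trace.
#'
#' @inheritParams simulate_state_trace
#' @param n_emitters number of emitters.
#' @return an object of class `state_traces`: a list with `fractions` (an
#'   `n_emitters x n_frames` matrix), `bleach_frame` (integer vector), and
#'   `dwells` (pooled completed on/off dwell times).
#' @export
simulate_state_traces <- function(params, frame_time_s, n_frames, n_emitters,
                                  seed, binary_sampling = FALSE) {
  if (n_emitters < 0) stop("n_emitters must be nonnegative", call. = FALSE)
  with_stream_seed(seed, "photophysics", {
    fr <- matrix(0, nrow = n_emitters, ncol = n_frames)
    bf <- rep(NA_integer_, n_emitters)
    on_d <- vector("list", n_emitters); off_d <- vector("list", n_emitters)
    for (k in seq_len(n_emitters)) {
      tr <- simulate_state_trace_impl(params, frame_time_s, n_frames, binary_sampling)
      fr[k, ] <- tr$emissive_fraction
      bf[k] <- tr$bleach_frame
      on_d[[k]] <- tr$dwells$on; off_d[[k]] <- tr$dwells$off
    }
    structure(list(fractions = fr, bleach_frame = bf,
                   frame_time_s = frame_time_s, params = params,
                   dwells = list(on = unlist(on_d), off = unlist(off_d))),
              class = "state_traces")
  })
}

#' Frame-wise mean emissive fraction across emitters
#'
#' The average fluorescence per frame; with bleaching enabled it fades
#' approximately exponentially, and an exponential fit to this curve recovers
#' the bleaching time constant.
#'
#' @param traces a `state_traces` object or a numeric matrix
#'   (emitters x frames).
#' @return numeric vector of per-frame means.
#' @export
mean_fluorescence_decay <- function(traces) {
  fr <- if (inherits(traces, "state_traces")) traces$fractions else as.matrix(traces)
  if (is.null(dim(fr)) || nrow(fr) < 1) stop("need at least one trace", call. = FALSE)
  colMeans(fr)
}

#' Fit an exponential decay to a mean-fluorescence curve
#'
#' Fits `A * exp(-t / t_decay)` by nonlinear least squares (initialized from
#' a log-linear fit) and returns the decay time in seconds.
#'
#' @param decay per-frame mean fluorescence (from [mean_fluorescence_decay()]).
#' @param frame_time_s exposure time per frame, seconds.
#' @return list with `t_decay_s` and `amplitude`.
#' @export
fit_bleach_decay <- function(decay, frame_time_s) {
  t <- (seq_along(decay) - 0.5) * frame_time_s
  pos <- decay > 0
  if (sum(pos) < 3) stop("decay curve has too few positive values", call. = FALSE)
  lf <- lm(log(decay[pos]) ~ t[pos])
  start <- list(A = exp(coef(lf)[1]), td = max(-1 / coef(lf)[2], frame_time_s))
  fit <- nls(y ~ A * exp(-t / td), data = data.frame(y = decay, t = t),
             start = start, control = list(warnOnly = TRUE))
  cf <- coef(fit)
  list(t_decay_s = unname(cf["td"]), amplitude = unname(cf["A"]))
}
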