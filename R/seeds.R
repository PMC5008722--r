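#' Derive a child seed from a base seed
#'
#' All randomness in the simulator flows from one explicit integer seed.
#' Sub-stages (emitter placement, photophysics, camera noise, ...) each use a
#' child seed derived deterministically from the base seed and a stream label,
#' so that changing one stage's draws never perturbs another stage.
#'
#' The scheme is a fixed affine map modulo 2^31 - 1 applied to the base seed
#' plus a hash of the stream name; it is documented so runs can be reproduced
#' outside the package.
#'
#' @param seed integer base seed.
#' @param stream character stream label (e.g. `"sample"`, `"photophysics"`,
#'   `"camera"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(7, "camera")
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(as.integer(charToRaw(stream)) * (31 ^ (seq_along(charToRaw(stream)) %% 5)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% (2^31 - 1))
}

with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(split_seed(seed, stream), code)
}
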