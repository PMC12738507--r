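# Internal helpers shared across modules.

# Population (not sample) standard deviation; stable for short weight vectors.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from one master seed; per-stage seeds
#' are derived deterministically from it so that stages can be re-run in
#' isolation without disturbing each other's random streams. The result is
#' always a valid 32-bit integer seed.
#'
#' @param master Integer master seed.
#' @param stage Character tag naming the stage (e.g. `"split"`, `"epoch3"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483647)
}

# stop() with a consistent prefix naming the offending field.
bad_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x == floor(x))
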