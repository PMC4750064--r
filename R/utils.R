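# Internal helpers shared across modules.

# Round half away from zero; R's round() is banker's rounding, which would
# send a baseline of 2.5 to 2 instead of 3.
round_half_up <- function(x) floor(x + 0.5)

#' Derive a reproducible sub-seed for a named random stream
#'
#' Each generated table draws from its own stream so that adding one output
#' never perturbs another. The sub-seed is a deterministic function of the
#' master seed and the stream name, kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name (e.g. "particles").
#' @return An integer usable with [set.seed()].
#' @keywords internal
stream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h * 2654435.0) %% 2147483647)
}

# Percentage rendering used in reports: nearest integer, half rounds up,
# so 93.5% prints as "94%".
render_percent <- function(x) sprintf("%d%%", round_half_up(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
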