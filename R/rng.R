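#' Named deterministic random-number substreams
#'
#' A session draws randomness from several logically independent sources
#' (serving the ball, culture spiking, feedback scheduling, the layout
#' bandit). Each source gets its own substream, seeded deterministically
#' from the session seed, so that enabling or disabling one component never
#' shifts the draws seen by another.
#'
#' A stream is an environment that stores a private copy of R's Mersenne
#' Twister state; [rng_eval()] swaps it in, evaluates an expression, and
#' swaps it back out, leaving the global RNG untouched.
#'
#' @param seed integer seed for this stream.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  e$ambient <- FALSE
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  restore_global_rng(old)
  class(e) <- "rng_stream"
  e
}

#' Derive a named substream from a master seed
#'
#' The substream seed is a deterministic hash of the master seed and the
#' stream name, kept within the 32-bit signed integer range.
#'
#' @param seed master (session) seed.
#' @param name character name of the substream.
#' @return an `rng_stream`.
#' @export
rng_substream <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  rng_stream((as.double(seed) * 48271 + h) %% 2147483647)
}

restore_global_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param stream an `rng_stream`.
#' @param expr expression to evaluate; any random draws inside it consume
#'   (and advance) the stream's private state.
#' @return the value of `expr`.
#' @export
rng_eval <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    restore_global_rng(old)
  })
  expr
}

# Evaluate expr drawing directly from the stream if it is already the
# ambient RNG (hot loops mark this with stream$ambient), else swap it in.
# The consumed draw sequence is identical either way.
rng_draw <- function(stream, expr) {
  if (stream$ambient) expr else rng_eval(stream, expr)
}
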