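# Shared fixtures, built in code at test time.

# straight-line ball trajectory with specular reflection: independent
# oracle for the game physics (no paddle interaction, open field)
reflect_1d <- function(x, lo, hi) {
  span <- 2 * (hi - lo)
  y <- (x - lo) %% span
  lo + ifelse(y > (hi - lo), span - y, y)
}

# closed-form ball position after n ticks ignoring the paddle
free_ball_position <- function(ball, config, n) {
  list(x = reflect_1d(ball$x + n * ball$vx, 0, config$field_width),
       y = reflect_1d(ball$y + n * ball$vy, 0, config$field_height))
}

# tiny deterministic raster: events at given (channel, time) pairs
raster_events <- function(channel, time_s, amplitude = -20) {
  data.frame(channel = as.integer(channel), time_s = as.numeric(time_s),
             amplitude = rep_len(amplitude, length(channel)))
}

# brute-force 2-D DCT-II (orthonormal), direct basis summation
dct2_brute <- function(img, u, v) {
  nr <- nrow(img); nc <- ncol(img)
  au <- if (u == 0) sqrt(1 / nr) else sqrt(2 / nr)
  av <- if (v == 0) sqrt(1 / nc) else sqrt(2 / nc)
  acc <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc))
    acc <- acc + img[i, j] *
      cos(pi * (2 * (i - 1) + 1) * u / (2 * nr)) *
      cos(pi * (2 * (j - 1) + 1) * v / (2 * nc))
  au * av * acc
}

run_short_session <- function(condition = "stimulus", seed = 1,
                              duration_min = 2, ...) {
  run_session(session_config(condition, seed = seed,
                             duration_min = duration_min, ...))
}
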