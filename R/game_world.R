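#' Game configuration
#'
#' The playing field is normalized to 100 x 100 length units so that ball
#' position can be read directly as a percentage of field traversal, which
#' keeps the place and rate codes dimensionless. The game advances in
#' discrete 10 ms ticks (100 ticks per second), matching the spike-count
#' bin of the recording side. The paddle sits on the right-hand wall
#' (`x = field_width`); the opposing wall is `x = 0`.
#'
#' Ball speed defaults to a wall-to-wall traverse in 6 s (600 ticks).
#' Paddle geometry (half-height 12.5 units, 1 unit of travel per tick) is
#' a configurable default chosen so the paddle covers a quarter of the
#' field height and can out-run any admissible ball vertical velocity.
#'
#' @param field_width,field_height field size in length units.
#' @param ball_speed ball speed, units per tick.
#' @param paddle_half_height half the paddle extent, units.
#' @param paddle_step paddle travel per commanded tick, units.
#' @param ticks_per_second game update rate; 100 gives 10 ms ticks.
#' @param long_rally_threshold rallies with strictly more hits than this
#'   count as long rallies.
#' @param serve_max_angle half-width of the serve cone about the
#'   horizontal, degrees; must be < 90 so serves are never vertical.
#' @return an object of class `game_config`.
#' @export
game_config <- function(field_width = 100, field_height = 100,
                        ball_speed = 100 / 600,
                        paddle_half_height = 12.5,
                        paddle_step = 1,
                        ticks_per_second = 100,
                        long_rally_threshold = 3,
                        serve_max_angle = 60) {
  cfg <- list(field_width = field_width, field_height = field_height,
              ball_speed = ball_speed,
              paddle_half_height = paddle_half_height,
              paddle_step = paddle_step,
              ticks_per_second = ticks_per_second,
              long_rally_threshold = long_rally_threshold,
              serve_max_angle = serve_max_angle)
  vals <- unlist(cfg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all game_config values must be finite and positive")
  if (paddle_half_height >= field_height / 2)
    stop("paddle_half_height must be < field_height/2")
  if (long_rally_threshold < 1) stop("long_rally_threshold must be >= 1")
  if (serve_max_angle >= 90) stop("serve cone must exclude vertical serves")
  structure(cfg, class = "game_config")
}

#' Serve the ball
#'
#' Places the ball at the field centre and launches it at full speed on a
#' random vector: the launch angle is uniform in a cone of
#' `serve_max_angle` degrees about the horizontal, with the horizontal
#' direction itself chosen at random, so near-vertical trajectories are
#' excluded and `vx` is never zero.
#'
#' @param rng an [rng_stream()] (the serve substream).
#' @param config a [game_config()].
#' @return a list with `x`, `y`, `vx`, `vy` (the ball state).
#' @export
serve_ball <- function(rng, config) {
  ang <- rng_eval(rng, {
    a <- runif(1, -config$serve_max_angle, config$serve_max_angle) * pi / 180
    if (runif(1) < 0.5) a <- pi - a
    a
  })
  list(x = config$field_width / 2, y = config$field_height / 2,
       vx = config$ball_speed * cos(ang),
       vy = config$ball_speed * sin(ang))
}

#' Initial game state
#'
#' The ball is served from the centre; the paddle starts at a uniformly
#' random admissible height. A fixed (e.g. centred) start would give
#' every session an early hit-rate advantage that decays as the paddle
#' diffuses toward its stationary position distribution, contaminating
#' within-session performance contrasts with a spurious decline.
#'
#' @param rng serve substream.
#' @param config a [game_config()].
#' @return a list with `ball`, `paddle_y` and `tick`.
#' @export
game_init <- function(rng, config) {
  h <- config$paddle_half_height
  list(ball = serve_ball(rng, config),
       paddle_y = rng_eval(rng, runif(1, h, config$field_height - h)),
       tick = 0L)
}

#' Advance the game by one 10 ms tick
#'
#' Moves the paddle one step in the commanded direction (clamped so it
#' stays fully inside the field), then advances the ball, reflecting it
#' specularly off the top, bottom and opposing walls. When the ball
#' reaches the paddle plane it is either returned (`paddle_hit`, if the
#' ball is within the paddle's vertical extent) or lost (`miss`). Under
#' the no-feedback condition the miss is still logged but the ball
#' reflects off the back wall and play continues, so the whole session is
#' one uninterrupted rally.
#'
#' @param state game state as returned by [game_init()] / previous ticks.
#' @param paddle_command one of `"up"`, `"down"`, `"none"`.
#' @param config a [game_config()].
#' @param no_feedback logical; if `TRUE`, misses bounce instead of
#'   terminating the rally.
#' @return list with `state` (advanced) and `events` (character vector,
#'   subset of `c("wall_bounce", "paddle_hit", "miss")`).
#' @export
game_tick <- function(state, paddle_command, config, no_feedback = FALSE) {
  b <- state$ball
  if (!all(is.finite(c(b$x, b$y, b$vx, b$vy, state$paddle_y))))
    stop("non-finite game state")
  events <- character(0)

  step <- switch(paddle_command, up = config$paddle_step,
                 down = -config$paddle_step, none = 0,
                 stop("unknown paddle command: ", paddle_command))
  py <- min(max(state$paddle_y + step, config$paddle_half_height),
            config$field_height - config$paddle_half_height)

  x <- b$x + b$vx
  y <- b$y + b$vy

  if (y < 0) { y <- -y; b$vy <- -b$vy; events <- c(events, "wall_bounce") }
  if (y > config$field_height) {
    y <- 2 * config$field_height - y; b$vy <- -b$vy
    events <- c(events, "wall_bounce")
  }
  if (x < 0) { x <- -x; b$vx <- -b$vx; events <- c(events, "wall_bounce") }
  if (x > config$field_width) {
    hit <- abs(y - py) <= config$paddle_half_height
    if (hit) {
      x <- 2 * config$field_width - x; b$vx <- -b$vx
      events <- c(events, "paddle_hit")
    } else {
      events <- c(events, "miss")
      if (no_feedback) {
        x <- 2 * config$field_width - x; b$vx <- -b$vx
      } else {
        x <- config$field_width
      }
    }
  }
  b$x <- x; b$y <- y
  list(state = list(ball = b, paddle_y = py, tick = state$tick + 1L),
       events = events)
}

#' Summarize rally records into gameplay performance metrics
#'
#' Average rally length is defined as total hits divided by the number of
#' rallies (the hit-miss ratio); aces are rallies with zero hits; long
#' rallies have strictly more than `long_rally_threshold` hits.
#'
#' @param records data.frame with at least a `hits` column (one row per
#'   rally), as produced by [run_session()].
#' @param paddle_distance optional total absolute paddle displacement over
#'   the session, field units.
#' @param long_rally_threshold threshold for long rallies (default 3).
#' @return an object of class `gameplay_summary`: list with
#'   `n_rallies`, `avg_rally_length`, `aces`, `long_rallies`,
#'   `paddle_distance`.
#' @export
summarize_rallies <- function(records, paddle_distance = NA_real_,
                              long_rally_threshold = 3) {
  if (NROW(records) == 0) stop("no rally records")
  hits <- records$hits
  structure(list(
    n_rallies = length(hits),
    avg_rally_length = sum(hits) / length(hits),
    aces = sum(hits == 0),
    long_rallies = sum(hits > long_rally_threshold),
    paddle_distance = paddle_distance
  ), class = "gameplay_summary")
}

#' @export
print.gameplay_summary <- function(x, ...) {
  cat("Gameplay summary\n")
  cat(sprintf("  rallies:          %d\n", x$n_rallies))
  cat(sprintf("  avg rally length: %.3f hits\n", x$avg_rally_length))
  cat(sprintf("  aces:             %d\n", x$aces))
  cat(sprintf("  long rallies:     %d\n", x$long_rallies))
  if (is.finite(x$paddle_distance))
    cat(sprintf("  paddle distance:  %.1f units\n", x$paddle_distance))
  invisible(x)
}
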