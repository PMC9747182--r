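#' Session configuration
#'
#' @param condition feedback condition: `"stimulus"`, `"silent"`,
#'   `"no_feedback"` or `"rest"`.
#' @param seed integer session seed (mandatory); all randomness in the
#'   session derives from it through named substreams, so a (config,
#'   seed) pair fully determines every log.
#' @param profile culture profile name (see [culture_profile()]).
#' @param layout_id motor layout preset, 0..4 (ignored when the bandit
#'   is enabled).
#' @param bandit logical; select the motor layout per rally with EXP3.
#' @param bandit_gamma EXP3 exploration rate.
#' @param duration_min session duration, minutes (at most 90: cultures
#'   do not tolerate longer testing).
#' @param resolution spike bookkeeping: `"region"` (aggregate counts
#'   only; fast) or `"channel"` (full per-channel event log with signed
#'   amplitudes, required for the raster analyses).
#' @param game a [game_config()].
#' @param profile_options named list of overrides passed to
#'   [culture_profile()].
#' @param exclude_first_s seconds of spiking excluded from
#'   electrophysiological analyses at the start of a session.
#' @return an object of class `session_config`.
#' @export
session_config <- function(condition = c("stimulus", "silent",
                                         "no_feedback", "rest"),
                           seed,
                           profile = "learner_human",
                           layout_id = 3L,
                           bandit = FALSE,
                           bandit_gamma = 0.1,
                           duration_min = 20,
                           resolution = c("region", "channel"),
                           game = game_config(),
                           profile_options = list(),
                           exclude_first_s = 10) {
  condition <- match.arg(condition)
  resolution <- match.arg(resolution)
  if (missing(seed)) stop("a session seed is mandatory")
  if (duration_min <= 0 || duration_min > 90)
    stop("duration must be in (0, 90] minutes")
  structure(list(condition = condition, seed = as.integer(seed),
                 profile = profile, layout_id = as.integer(layout_id),
                 bandit = bandit, bandit_gamma = bandit_gamma,
                 duration_min = duration_min, resolution = resolution,
                 game = game, profile_options = profile_options,
                 exclude_first_s = exclude_first_s),
            class = "session_config")
}

grow <- function(buf, need) {
  while (length(buf) < need) length(buf) <- max(2L * length(buf), 64L)
  buf
}

#' Run one closed-loop session
#'
#' Executes the full loop tick-by-tick: sensory stimulation is planned
#' from the ball position (place and rate code), the virtual culture
#' responds, spikes are counted per motor region, gain-normalized and
#' decoded into a paddle command, the game advances, and rally outcomes
#' trigger condition-dependent feedback that both stimulates and updates
#' the culture. Under the rest condition the loop runs with the paddle
#' driven by spontaneous activity and no stimulation of any kind; under
#' no-feedback, sensory stimulation continues but misses bounce the ball
#' off the back wall, so the session is a single uninterrupted rally.
#'
#' @param config a [session_config()].
#' @return an object of class `pong_session`: list with `config`,
#'   `rallies` (rally records), `events` (game events), `stim_log`,
#'   `spikes` (channel resolution only), `bandit_trace`, `summary`
#'   (a [summarize_rallies()] result) and diagnostic culture/gain state.
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  game <- config$game
  tps <- game$ticks_per_second
  spt <- as.integer(round(20000 / tps))          # samples per tick
  n_ticks <- as.integer(config$duration_min * 60 * tps)
  duration_s <- config$duration_min * 60
  condition <- config$condition
  channel_mode <- config$resolution == "channel"
  stim_enabled <- condition %in% c("stimulus", "silent", "no_feedback")

  rs <- rng_substream(config$seed, "serve")
  rc <- rng_substream(config$seed, "culture")
  rf <- rng_substream(config$seed, "feedback")
  rb <- rng_substream(config$seed, "bandit")

  layouts <- lapply(0:4, electrode_layout)
  if (config$bandit) {
    bstate <- exp3_init(n_arms = 5L, gamma = config$bandit_gamma)
    sel <- exp3_select(bstate, rb)
    current_layout <- sel$arm - 1L
    current_prob <- sel$prob
  } else {
    current_layout <- config$layout_id
    current_prob <- NA_real_
  }
  layout <- layouts[[current_layout + 1L]]

  profile <- do.call(culture_profile,
                     c(list(name = config$profile), config$profile_options))
  culture <- culture_init(profile, layout, rc, duration_s, tps)
  gain <- gain_state()

  gstate <- game_init(rs, game)
  paddle_distance <- 0
  phase <- "rally"
  interlude_until <- -1L
  suppress_until <- -1L
  seq_next <- 0                       # sensory pulse phase accumulator

  # feedback pulse queue (absolute samples, sorted within/between plans)
  fbq_t <- numeric(0); fbq_s <- integer(0); fbq_a <- numeric(0)
  fbq_l <- character(0); fbq_ptr <- 1L

  # log buffers
  st_t <- numeric(256); st_s <- integer(256); st_a <- numeric(256)
  st_l <- character(256); st_n <- 0L
  ev_k <- character(256); ev_t <- integer(256); ev_n <- 0L
  sp_ch <- integer(1024); sp_tk <- integer(1024); sp_am <- numeric(1024)
  sp_lb <- character(1024); sp_n <- 0L
  rl <- list(); rl_n <- 0L
  bt <- list(); bt_n <- 0L

  rally_start <- 0L
  rally_hits <- 0L
  rally_index <- 1L

  push_event <- function(kind, tick) {
    ev_n <<- ev_n + 1L
    if (ev_n > length(ev_k)) { ev_k <<- grow(ev_k, ev_n); ev_t <<- grow(ev_t, ev_n) }
    ev_k[ev_n] <<- kind; ev_t[ev_n] <<- tick
  }
  queue_plan <- function(plan) {
    if (nrow(plan$pulses) == 0) return(invisible(NULL))
    keep <- if (fbq_ptr <= length(fbq_t)) fbq_ptr:length(fbq_t) else integer(0)
    fbq_t <<- c(fbq_t[keep], plan$pulses$start_sample)
    fbq_s <<- c(fbq_s[keep], plan$pulses$site)
    fbq_a <<- c(fbq_a[keep], plan$pulses$amplitude_mV)
    fbq_l <<- c(fbq_l[keep], rep.int(plan$label, nrow(plan$pulses)))
    fbq_ptr <<- 1L
    invisible(NULL)
  }

  push_event("serve", 0L)

  # gain bookkeeping inlined for speed; algebra identical to
  # update_gain() / gain_factors() / decode_motor()
  g_a <- (1 / tps) / gain$tau
  g_dt <- 1 / tps
  g1 <- gain$rate[[1]]; g2 <- gain$rate[[2]]
  g_lo <- gain$clamp[1]; g_hi <- gain$clamp[2]
  g_target <- gain$target_rate
  fw <- game$field_width; fh <- game$field_height

  rc$ambient <- TRUE
  on.exit(rc$ambient <- FALSE, add = TRUE)
  rng_eval(rc, for (tick in 0:(n_ticks - 1L)) {
    clock <- tick * spt
    p_sites <- integer(0); p_amps <- numeric(0); p_times <- numeric(0)
    p_labels <- character(0)

    # feedback pulses due in this bin
    while (fbq_ptr <= length(fbq_t) && fbq_t[fbq_ptr] < clock + spt) {
      p_sites <- c(p_sites, fbq_s[fbq_ptr])
      p_amps <- c(p_amps, fbq_a[fbq_ptr])
      p_times <- c(p_times, fbq_t[fbq_ptr])
      p_labels <- c(p_labels, fbq_l[fbq_ptr])
      fbq_ptr <- fbq_ptr + 1L
    }

    if (phase == "interlude" && tick >= interlude_until) {
      phase <- "rally"
      gstate$ball <- serve_ball(rs, game)
      rally_start <- tick
      rally_hits <- 0L
      seq_next <- clock
      push_event("serve", tick)
    }

    # sensory stimulation from the current ball position (rate_code and
    # place_code inlined)
    if (phase == "rally" && stim_enabled && tick >= suppress_until) {
      f <- 4 + 36 * (gstate$ball$x / fw)
      site <- min(gstate$ball$y %/% (fh / 8), 7)
      period <- 20000 / f
      if (seq_next < clock) seq_next <- clock
      while (seq_next < clock + spt) {
        p_sites <- c(p_sites, site)
        p_amps <- c(p_amps, 75)
        p_times <- c(p_times, seq_next)
        p_labels <- c(p_labels, "sensory")
        seq_next <- seq_next + period
      }
    }

    n_p <- length(p_sites)
    if (n_p > 0) {
      idx <- st_n + seq_len(n_p)
      if (idx[n_p] > length(st_t)) {
        st_t <- grow(st_t, idx[n_p]); st_s <- grow(st_s, idx[n_p])
        st_a <- grow(st_a, idx[n_p]); st_l <- grow(st_l, idx[n_p])
      }
      st_t[idx] <- p_times; st_s[idx] <- p_sites
      st_a[idx] <- p_amps; st_l[idx] <- p_labels
      st_n <- st_n + n_p
    }

    cs <- culture_step(culture,
                       if (n_p > 0) list(site = p_sites, amplitude_mV = p_amps)
                       else NULL,
                       tick, config$resolution)
    counts <- cs$counts

    if (channel_mode && length(cs$channels)) {
      k <- length(cs$channels)
      idx <- sp_n + seq_len(k)
      if (idx[k] > length(sp_ch)) {
        sp_ch <- grow(sp_ch, idx[k]); sp_tk <- grow(sp_tk, idx[k])
        sp_am <- grow(sp_am, idx[k]); sp_lb <- grow(sp_lb, idx[k])
      }
      sp_ch[idx] <- cs$channels; sp_tk[idx] <- tick
      sp_am[idx] <- cs$amplitudes; sp_lb[idx] <- cs$labels
      sp_n <- sp_n + k
    }

    c1 <- counts[[1L]]; c2 <- counts[[2L]]
    g1 <- (1 - g_a) * g1 + g_a * c1 / g_dt
    g2 <- (1 - g_a) * g2 + g_a * c2 / g_dt

    if (phase == "rally") {
      d1 <- c1 / min(max(g1 / g_target, g_lo), g_hi)
      d2 <- c2 / min(max(g2 / g_target, g_lo), g_hi)
      cmd <- if (d1 > d2) "up" else if (d2 > d1) "down" else "none"
      if (cmd != "none" && !is.null(culture$last_evoked))
        culture_credit(culture, if (cmd == "up") 1L else 2L, tick)
      old_py <- gstate$paddle_y
      gt <- game_tick(gstate, cmd, game,
                      no_feedback = condition == "no_feedback")
      gstate <- gt$state
      paddle_distance <- paddle_distance + abs(gstate$paddle_y - old_py)

      for (ev in gt$events) push_event(ev, tick)

      if ("paddle_hit" %in% gt$events) {
        rally_hits <- rally_hits + 1L
        if (condition %in% c("stimulus", "silent")) {
          plan <- plan_feedback("paddle_hit", condition, rf, clock)
          if (condition == "stimulus") {
            apply_feedback(culture, "predictable", tick)
          } else {
            # silent: the rally's predictable continuation is a weaker,
            # implicit reinforcement of the successful mapping
            apply_feedback(culture, "predictable", tick,
                           scale = profile$silent_hit_scale)
          }
          queue_plan(plan)
          suppress_until <- tick + as.integer(plan$duration_samples / spt)
        }
      }

      if ("miss" %in% gt$events && condition != "no_feedback") {
        rl_n <- rl_n + 1L
        rl[[rl_n]] <- list(rally_index = rally_index,
                           start_tick = rally_start, end_tick = tick,
                           hits = rally_hits, layout_id = current_layout,
                           condition = condition, outcome = "miss")
        if (config$bandit) {
          bstate <- exp3_update(bstate, current_layout + 1L,
                                rally_loss(rally_hits))
          bt_n <- bt_n + 1L
          bt[[bt_n]] <- list(round = rally_index, arm = current_layout,
                             score = rally_hits,
                             loss = rally_loss(rally_hits),
                             prob_of_chosen = current_prob)
          sel <- exp3_select(bstate, rb)
          if (sel$arm - 1L != current_layout) {
            current_layout <- sel$arm - 1L
            layout <- layouts[[current_layout + 1L]]
            culture_set_layout(culture, layout)
          } else current_layout <- sel$arm - 1L
          current_prob <- sel$prob
        }
        rally_index <- rally_index + 1L

        plan <- plan_feedback("miss", condition, rf, clock)
        apply_feedback(culture,
                       switch(condition, stimulus = "unpredictable",
                              silent = "silent_gap", rest = "none"),
                       tick)
        queue_plan(plan)
        dur_ticks <- as.integer(plan$duration_samples / spt)
        if (dur_ticks > 0) {
          phase <- "interlude"
          interlude_until <- tick + dur_ticks
        } else {
          gstate$ball <- serve_ball(rs, game)
          rally_start <- tick + 1L
          rally_hits <- 0L
          seq_next <- clock + spt
          push_event("serve", tick)
        }
      }
    }
  })
  rc$ambient <- FALSE
  gain$rate <- c(motor1 = g1, motor2 = g2)

  # close the open rally (always the case under no-feedback)
  if (phase == "rally") {
    rl_n <- rl_n + 1L
    rl[[rl_n]] <- list(rally_index = rally_index, start_tick = rally_start,
                       end_tick = n_ticks - 1L, hits = rally_hits,
                       layout_id = current_layout, condition = condition,
                       outcome = "session_end")
  }

  rallies <- do.call(rbind, lapply(rl, as.data.frame))
  events <- data.frame(kind = ev_k[seq_len(ev_n)], tick = ev_t[seq_len(ev_n)])
  stim_log <- data.frame(sample = as.integer(round(st_t[seq_len(st_n)])),
                         site = st_s[seq_len(st_n)],
                         amplitude_mV = st_a[seq_len(st_n)],
                         label = st_l[seq_len(st_n)])
  stim_log <- stim_log[order(stim_log$sample, stim_log$site), , drop = FALSE]
  rownames(stim_log) <- NULL
  spikes <- if (channel_mode) {
    data.frame(channel = sp_ch[seq_len(sp_n)],
               tick = sp_tk[seq_len(sp_n)],
               sample = sp_tk[seq_len(sp_n)] * spt,
               amplitude = sp_am[seq_len(sp_n)],
               label = sp_lb[seq_len(sp_n)])
  } else NULL
  bandit_trace <- if (bt_n > 0) do.call(rbind, lapply(bt, as.data.frame))
                  else NULL

  structure(list(
    config = config,
    rallies = rallies,
    events = events,
    stim_log = stim_log,
    spikes = spikes,
    bandit_trace = bandit_trace,
    summary = summarize_rallies(rallies, paddle_distance,
                                game$long_rally_threshold),
    paddle_distance = paddle_distance,
    final_coupling = culture$Wreg,
    final_gain = gain$rate,
    n_ticks = n_ticks
  ), class = "pong_session")
}

#' @export
print.pong_session <- function(x, ...) {
  cat(sprintf("Closed-loop session: %s / %s, %g min, seed %d\n",
              x$config$condition, x$config$profile,
              x$config$duration_min, x$config$seed))
  print(x$summary)
  invisible(x)
}
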