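#' Place code: ball height to stimulation site
#'
#' The vertical field span is partitioned into 8 equal half-open bins,
#' mapped bottom-to-top onto stimulation sites 0..7 (site 0 is the lowest
#' band; this bottom-to-top order is a configuration convention of the
#' simulator). The top edge maps to site 7.
#'
#' @param ball_y ball height, field units (may be vectorized).
#' @param field_height field height.
#' @param n_sites number of stimulation sites (8).
#' @return integer site index in `0:(n_sites-1)`.
#' @export
place_code <- function(ball_y, field_height, n_sites = 8L) {
  if (any(ball_y < 0 | ball_y > field_height))
    stop("ball_y outside [0, field_height]")
  pmin(as.integer(floor(ball_y / field_height * n_sites)), n_sites - 1L)
}

#' Rate code: ball distance to stimulation frequency
#'
#' Stimulation frequency rises linearly from 4 Hz when the ball is at the
#' opposing wall to 40 Hz when it reaches the paddle wall.
#'
#' @param distance distance of the ball from the opposing wall, field
#'   units (equals ball `x` with the paddle on the right wall).
#' @param field_width field width.
#' @return frequency in Hz, in `[4, 40]`.
#' @export
rate_code <- function(distance, field_width) {
  if (any(distance < 0 | distance > field_width))
    stop("distance outside [0, field_width]")
  4 + 36 * (distance / field_width)
}

#' Construct a stimulation plan
#'
#' @param pulses data.frame with columns `site`, `start_sample`,
#'   `amplitude_mV`, `phase_us`.
#' @param label one of `"sensory"`, `"predictable"`, `"unpredictable"`,
#'   `"silent_gap"`, `"none"`.
#' @param duration_samples span of the plan at 20 kHz.
#' @return an object of class `stim_plan`.
#' @export
stim_plan <- function(pulses, label, duration_samples = 0L) {
  stopifnot(label %in% c("sensory", "predictable", "unpredictable",
                         "silent_gap", "none"))
  if (NROW(pulses) > 1 && is.unsorted(pulses$start_sample))
    pulses <- pulses[order(pulses$start_sample), , drop = FALSE]
  if (label %in% c("silent_gap", "none") && NROW(pulses) != 0)
    stop("silent_gap/none plans must contain no pulses")
  structure(list(pulses = pulses, label = label,
                 duration_samples = as.integer(duration_samples)),
            class = "stim_plan")
}

empty_pulses <- function() {
  data.frame(site = integer(0), start_sample = integer(0),
             amplitude_mV = numeric(0), phase_us = numeric(0))
}

#' Plan sensory stimulation for the coming spike-count bin
#'
#' Emits biphasic pulse commands on the place-coded site at the rate-coded
#' frequency for the current ball position, covering `horizon_samples`
#' of the 20 kHz clock (one 10 ms bin = 200 samples by default). A phase
#' accumulator (`next_sample` in the sequencer state) carries pulse timing
#' across refreshes so that re-planning at a bin or rate boundary never
#' doubles the instantaneous frequency.
#'
#' @param ball list with `x`, `y` (ball state).
#' @param seq_state sequencer state: list with `next_sample`, or `NULL`
#'   to start at `clock_sample`.
#' @param clock_sample current 20 kHz sample index.
#' @param config a [game_config()].
#' @param active logical; `FALSE` (rally not in play) yields an empty plan.
#' @param horizon_samples planning horizon.
#' @param amplitude_mV sensory pulse amplitude (75 mV).
#' @param phase_us biphasic phase duration, microseconds per phase.
#' @return list with `plan` (a [stim_plan()]) and `seq_state`.
#' @export
plan_sensory <- function(ball, seq_state, clock_sample, config,
                         active = TRUE, horizon_samples = 200L,
                         amplitude_mV = 75, phase_us = 200) {
  if (!active) {
    return(list(plan = stim_plan(empty_pulses(), "none"),
                seq_state = seq_state))
  }
  if (is.null(seq_state)) seq_state <- list(next_sample = clock_sample)
  f <- rate_code(ball$x, config$field_width)
  site <- place_code(ball$y, config$field_height)
  period <- 20000 / f
  horizon_end <- clock_sample + horizon_samples
  times <- numeric(0)
  nxt <- max(seq_state$next_sample, clock_sample)
  while (nxt < horizon_end) {
    times <- c(times, nxt)
    nxt <- nxt + period
  }
  seq_state$next_sample <- nxt
  pulses <- data.frame(site = rep.int(site, length(times)),
                       start_sample = as.integer(round(times)),
                       amplitude_mV = rep.int(amplitude_mV, length(times)),
                       phase_us = rep.int(phase_us, length(times)))
  list(plan = stim_plan(pulses, "sensory", horizon_samples),
       seq_state = seq_state)
}

#' Plan outcome feedback stimulation
#'
#' Under the stimulus condition a miss triggers the unpredictable
#' stimulus: 4 s of 150 mV pulses at random sites with exponential
#' inter-pulse gaps averaging 200 ms (5 Hz aggregate; the memoryless gap
#' law is the maximally unpredictable schedule consistent with that
#' rate), followed by a 4 s rest with no stimulation. A hit triggers the
#' predictable stimulus: all 8 sites synchronously at 100 Hz for 100 ms
#' at 75 mV, replacing sensory stimulation for its duration. The silent
#' condition spans the same intervals with zero pulses (it suppresses
#' both feedback stimuli), and no-feedback returns a zero-length plan so
#' play continues uninterrupted.
#'
#' @param event `"paddle_hit"` or `"miss"`.
#' @param condition one of `"stimulus"`, `"silent"`, `"no_feedback"`,
#'   `"rest"`.
#' @param rng feedback substream ([rng_stream()]).
#' @param clock_sample 20 kHz sample at which the plan starts.
#' @param n_sites number of stimulation sites.
#' @param phase_us biphasic phase duration, microseconds.
#' @return a [stim_plan()]; its `duration_samples` is the interval during
#'   which normal play/sensory coding is suspended.
#' @export
plan_feedback <- function(event, condition, rng, clock_sample = 0L,
                          n_sites = 8L, phase_us = 200) {
  stopifnot(event %in% c("paddle_hit", "miss"))
  fs <- 20000
  if (condition == "stimulus") {
    if (event == "miss") {
      times <- rng_eval(rng, {
        t <- clock_sample + cumsum(rexp(80, rate = 5) * fs)
        t[t < clock_sample + 4 * fs]
      })
      sites <- rng_eval(rng, sample.int(n_sites, length(times),
                                        replace = TRUE) - 1L)
      pulses <- data.frame(site = sites,
                           start_sample = as.integer(round(times)),
                           amplitude_mV = rep.int(150, length(times)),
                           phase_us = rep.int(phase_us, length(times)))
      stim_plan(pulses, "unpredictable", 8L * fs)
    } else {
      t0 <- rep(clock_sample + (0:9) * (fs / 100), each = n_sites)
      pulses <- data.frame(site = rep.int(0:(n_sites - 1L), 10),
                           start_sample = as.integer(round(t0)),
                           amplitude_mV = rep.int(75, 10 * n_sites),
                           phase_us = rep.int(phase_us, 10 * n_sites))
      stim_plan(pulses, "predictable", as.integer(0.1 * fs))
    }
  } else if (condition == "silent") {
    dur <- if (event == "miss") 8L * fs else as.integer(0.1 * fs)
    stim_plan(empty_pulses(), "silent_gap", dur)
  } else if (condition %in% c("no_feedback", "rest")) {
    stim_plan(empty_pulses(), "none", 0L)
  } else {
    stop("unknown feedback condition: ", condition)
  }
}
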