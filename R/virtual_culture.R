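#' Virtual-culture profiles
#'
#' The virtual culture is a deliberately minimal emulation of an MEA
#' recording from a cultured network: per-channel baseline Poisson firing
#' with a log-normal rate map, stimulation-evoked responses with latency
#' jitter routed through a site-by-channel coupling matrix, occasional
#' synchronized population bursts, and feedback-gated plasticity on the
#' coupling. Its purpose is to exercise the closed-loop mechanics, not to
#' model biophysics: every closed-loop property of the simulator should
#' be attributable to the embodiment machinery, not to culture-model
#' sophistication.
#'
#' Profiles:
#' * `learner_human` - active culture with evoked responses and plasticity
#'   (the standard experimental profile).
#' * `learner_mouse` - as above with weaker evoked gain and plasticity.
#' * `media_only` - electrode noise floor of a cell-free MEA: sparse
#'   false-positive events, no evoked response, no plasticity.
#' * `inactive_cells` - electrically near-silent cells.
#' * `in_silico_random` - control that bypasses the culture: motor counts
#'   are iid Poisson noise at healthy rates, with no stimulus coupling
#'   and no plasticity, so the paddle is driven by pure noise.
#'
#' The feedback-update rates encode the qualitative ordering of the
#' feedback conditions as tunable defaults: the predictable stimulus
#' potentiates eligible couplings (`eta_potentiate`), the unpredictable
#' stimulus perturbs them multiplicatively (`eta_perturb`), and a silent
#' gap perturbs in the same direction but more weakly
#' (`eta_silent < eta_perturb`).
#'
#' @param name profile name (see above).
#' @param baseline_median_hz median per-channel baseline rate, Hz.
#' @param baseline_sdlog log-normal spread of the channel rate map.
#' @param asymmetry relative motor1/motor2 baseline imbalance: motor1
#'   channel rates are scaled by `1 + asymmetry`, motor2 by
#'   `1/(1 + asymmetry)`.
#' @param evoked_gain expected evoked spikes per 75 mV stimulation pulse
#'   (summed over all channels); scales linearly with pulse voltage.
#' @param eta_potentiate,eta_perturb,eta_silent plasticity rates.
#' @param silent_hit_scale attenuation of hit potentiation under the
#'   silent condition, where reinforcement is only implicit (the rally's
#'   predictable continuation), in `[0, 1]`.
#' @param elig_tau_s eligibility-trace decay constant, seconds.
#' @param w_max elementwise coupling bound.
#' @param burst_rate_hz rate of synchronized population bursts, Hz.
#' @param burst_duration_s burst duration, seconds.
#' @param burst_boost_hz added per-channel rate during a burst, Hz.
#' @return an object of class `culture_profile`.
#' @export
culture_profile <- function(name = c("learner_human", "learner_mouse",
                                     "media_only", "inactive_cells",
                                     "in_silico_random"),
                            baseline_median_hz = NULL,
                            baseline_sdlog = 0.8,
                            asymmetry = 0,
                            evoked_gain = NULL,
                            eta_potentiate = NULL,
                            eta_perturb = NULL,
                            eta_silent = NULL,
                            silent_hit_scale = 0.3,
                            elig_tau_s = 2,
                            w_max = 0.05,
                            burst_rate_hz = NULL,
                            burst_duration_s = 0.3,
                            burst_boost_hz = 10) {
  name <- match.arg(name)
  defaults <- switch(name,
    learner_human = list(rate = 0.25, gain = 30, pot = 0.5, pert = 0.05,
                         sil = 0.02,  burst = 0.1),
    learner_mouse = list(rate = 0.25, gain = 18, pot = 0.3, pert = 0.05,
                         sil = 0.02,  burst = 0.1),
    media_only     = list(rate = 0.05, gain = 0, pot = 0, pert = 0,
                          sil = 0,    burst = 0),
    inactive_cells = list(rate = 0.01, gain = 0, pot = 0, pert = 0,
                          sil = 0,    burst = 0),
    in_silico_random = list(rate = 0.25, gain = 0, pot = 0, pert = 0,
                            sil = 0,  burst = 0))
  p <- list(
    name = name,
    baseline_median_hz = baseline_median_hz %||% defaults$rate,
    baseline_sdlog = baseline_sdlog,
    asymmetry = asymmetry,
    evoked_gain = evoked_gain %||% defaults$gain,
    eta_potentiate = eta_potentiate %||% defaults$pot,
    eta_perturb = eta_perturb %||% defaults$pert,
    eta_silent = eta_silent %||% defaults$sil,
    silent_hit_scale = silent_hit_scale,
    elig_tau_s = elig_tau_s,
    w_max = w_max,
    burst_rate_hz = burst_rate_hz %||% defaults$burst,
    burst_duration_s = burst_duration_s,
    burst_boost_hz = burst_boost_hz,
    bypass = (name == "in_silico_random"))
  if (p$name %in% c("media_only", "inactive_cells", "in_silico_random") &&
      (p$evoked_gain != 0 || p$eta_potentiate != 0 || p$eta_perturb != 0))
    stop("control profiles must have zero evoked gain and zero plasticity")
  if (any(unlist(p[c("baseline_median_hz", "evoked_gain", "eta_potentiate",
                     "eta_perturb", "eta_silent", "burst_rate_hz")]) < 0))
    stop("rates must be >= 0")
  structure(p, class = "culture_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a culture profile as JSON
#'
#' Profiles round-trip through plain JSON files; presets for the five
#' named profiles ship under `inst/extdata/profiles/`.
#'
#' @param profile a [culture_profile()].
#' @param path file path.
#' @return `read_culture_profile` returns a validated `culture_profile`.
#' @export
write_culture_profile <- function(profile, path) {
  jsonlite::write_json(unclass(profile)[setdiff(names(profile), "bypass")],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_culture_profile
#' @export
read_culture_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(culture_profile, j)
}

#' Initialize the virtual-culture state
#'
#' Draws the per-channel baseline rate map (log-normal, skewed as real
#' rate maps are), the initial site-by-channel coupling (each site's
#' couplings jittered around a uniform profile and normalized to unit
#' total, so one 75 mV pulse initially evokes `evoked_gain` spikes
#' network-wide with no preferred direction), and the burst schedule for
#' the session. The state is an environment and is mutated in place by
#' [culture_step()] and [apply_feedback()].
#'
#' @param profile a [culture_profile()].
#' @param layout an [electrode_layout()].
#' @param rng culture substream ([rng_stream()]).
#' @param duration_s session duration covered by the burst schedule.
#' @param ticks_per_second game tick rate (100).
#' @return an environment of class `culture_state`.
#' @export
culture_init <- function(profile, layout, rng, duration_s = 1200,
                         ticks_per_second = 100) {
  st <- new.env(parent = emptyenv())
  st$profile <- profile
  st$layout <- layout
  st$rng <- rng
  st$dt <- 1 / ticks_per_second
  n_ch <- nrow(layout$channels)
  reg <- layout$channels$region
  st$region_index <- match(reg, c("motor1", "motor2", "sensory"))

  st$rates <- rng_eval(rng, {
    r <- stats::rlnorm(n_ch, meanlog = log(profile$baseline_median_hz),
                       sdlog = profile$baseline_sdlog)
    r[reg == "motor1"] <- r[reg == "motor1"] * (1 + profile$asymmetry)
    r[reg == "motor2"] <- r[reg == "motor2"] / (1 + profile$asymmetry)
    r
  })
  st$region_rates <- c(
    motor1 = sum(st$rates[reg == "motor1"]),
    motor2 = sum(st$rates[reg == "motor2"]),
    sensory = sum(st$rates[reg == "sensory"]))
  st$region_n <- tabulate(st$region_index, 3)

  n_sites <- length(layout$stim_sites)
  st$W <- rng_eval(rng, matrix(stats::rlnorm(n_sites * n_ch, 0, 0.25),
                               n_sites, n_ch))
  st$W <- st$W / rowSums(st$W)
  # balance the initial motor couplings: with no training the culture has
  # no preferred direction, so each site's total coupling to motor 1 and
  # motor 2 is equalized (channel-count differences between the regions
  # would otherwise give every site a fixed directional bias)
  wr <- region_sums(st$W, st$region_index)
  for (r in 1:2) {
    cols <- which(st$region_index == r)
    st$W[, cols] <- st$W[, cols] * ((wr[, 1] + wr[, 2]) / 2) / wr[, r]
  }
  st$W <- st$W / rowSums(st$W)
  st$Wreg <- region_sums(st$W, st$region_index)

  st$elig <- matrix(0, n_sites, 3)   # columns: motor1, motor2, sensory
  st$elig_tick <- 0L

  n_ticks <- as.integer(ceiling(duration_s * ticks_per_second))
  st$burst_active <- rep(FALSE, n_ticks)
  if (profile$burst_rate_hz > 0) {
    starts <- rng_eval(rng, {
      n <- stats::rpois(1, profile$burst_rate_hz * duration_s)
      sort(stats::runif(n, 0, duration_s))
    })
    len <- as.integer(profile$burst_duration_s * ticks_per_second)
    for (s in starts) {
      i0 <- as.integer(s * ticks_per_second) + 1L
      ii <- i0:min(i0 + len - 1L, n_ticks)
      st$burst_active[ii] <- TRUE
    }
  }
  # pending evoked spikes by landing tick (modulo the latency horizon),
  # keeping their stimulation-site attribution for eligibility crediting
  st$horizon <- 4L
  st$pending_sr <- array(0, c(st$horizon, n_sites, 3))
  st$pending_any <- rep(FALSE, st$horizon)
  st$pending_channels <- vector("list", st$horizon)
  st$last_evoked <- NULL       # site x region evoked spikes landed this bin
  class(st) <- "culture_state"
  st
}

#' Re-assign the culture to a different motor layout
#'
#' The per-channel rate map and couplings are properties of the culture
#' and stay fixed; only the region bookkeeping (used for decoding and
#' aggregate draws) follows the new layout. Eligibility traces are reset
#' because their region attribution is no longer meaningful.
#'
#' @param state a `culture_state` environment.
#' @param layout the new [electrode_layout()].
#' @return the state, invisibly.
#' @export
culture_set_layout <- function(state, layout) {
  reg <- layout$channels$region
  state$layout <- layout
  state$region_index <- match(reg, REGION_NAMES)
  state$region_rates <- c(motor1 = sum(state$rates[reg == "motor1"]),
                          motor2 = sum(state$rates[reg == "motor2"]),
                          sensory = sum(state$rates[reg == "sensory"]))
  state$region_n <- tabulate(state$region_index, 3)
  state$Wreg <- region_sums(state$W, state$region_index)
  state$elig[] <- 0
  invisible(state)
}

region_sums <- function(W, region_index) {
  out <- matrix(0, nrow(W), 3)   # columns: motor1, motor2, sensory
  for (r in 1:3) {
    cols <- which(region_index == r)
    out[, r] <- rowSums(W[, cols, drop = FALSE])
  }
  out
}

# latency kernel: probability that an evoked spike lands 0..3 ticks after
# its pulse (mean latency ~9 ms with jitter)
EVOKED_DELAY_PROBS <- c(0.40, 0.35, 0.20, 0.05)

#' Advance the virtual culture by one 10 ms bin
#'
#' Per-channel spike counts follow an inhomogeneous Poisson law: the
#' baseline rate map (elevated during synchronized bursts), plus, for
#' each recent stimulation pulse on site s, an evoked response with
#' expected size `evoked_gain * (amplitude / 75 mV)` distributed across
#' channels in proportion to the coupling `W[s, ]` and across time by a
#' short latency kernel. The evoked spikes that land in the bin are
#' exposed (by stimulation site and region) in `state$last_evoked` so
#' that [culture_credit()] can build the action-gated eligibility trace.
#'
#' At `resolution = "region"` only the three region aggregate counts are
#' drawn (sufficient for closed-loop decoding and fast enough for long
#' batches of sessions); at `"channel"` every event carries its channel,
#' a signed amplitude in microvolts, and a ground-truth label
#' (`spont`/`evoked`/`burst`) for detector validation.
#'
#' @param state a [culture_init()] environment (mutated in place).
#' @param pulses pulses commanded in this bin: a list (or data.frame)
#'   with `site` (0-based) and `amplitude_mV`; may be `NULL`.
#' @param tick 0-based tick index (indexes the burst schedule).
#' @param resolution `"region"` or `"channel"`.
#' @return list with `counts` (named motor1/motor2/sensory) and, at
#'   channel resolution, `channels` (0-based, one entry per spike),
#'   `amplitudes` (signed microvolts) and `labels`
#'   (`spont`/`burst`/`evoked`); use [culture_events()] for a
#'   data.frame view.
#' @export
culture_step <- function(state, pulses, tick, resolution = "region") {
  rng_draw(state$rng, culture_step_impl(state, pulses, tick, resolution))
}

culture_step_impl <- function(state, pulses, tick, resolution) {
  dt <- state$dt
  burst <- state$burst_active[tick + 1L]
  if (is.na(burst)) burst <- FALSE   # tick beyond the prepared schedule
  slot <- (tick %% state$horizon) + 1L
  channel_mode <- resolution == "channel"

  if (!channel_mode) {
    lam <- state$region_rates * dt
    if (burst) lam <- lam + state$profile$burst_boost_hz * dt * state$region_n
    counts <- rpois(3, lam)
    ch <- NULL; lab <- NULL
  } else {
    lam <- state$rates * dt
    if (burst) lam <- lam + state$profile$burst_boost_hz * dt
    ch_counts <- rpois(length(lam), lam)
    active <- which(ch_counts > 0L)
    ch <- rep.int(active - 1L, ch_counts[active])
    counts <- tabulate(state$region_index[ch + 1L], 3)
    lab <- rep.int(if (burst) "burst" else "spont", length(ch))
  }

  # evoked spikes landing now, scheduled by earlier pulses
  landed <- NULL
  if (state$pending_any[slot]) {
    landed <- state$pending_sr[slot, , ]
    counts <- counts + colSums(landed)
    if (channel_mode && length(state$pending_channels[[slot]])) {
      pc <- state$pending_channels[[slot]]
      ch <- c(ch, pc)
      lab <- c(lab, rep.int("evoked", length(pc)))
    }
    state$pending_sr[slot, , ] <- 0
    state$pending_any[slot] <- FALSE
    state$pending_channels[slot] <- list(NULL)
  }

  n_pulse <- if (is.null(pulses)) 0L else length(pulses$site)
  if (n_pulse > 0 && state$profile$evoked_gain > 0) {
    gain <- state$profile$evoked_gain
    Wreg <- state$Wreg
    horizon <- state$horizon
    for (i in seq_len(n_pulse)) {
      s <- pulses$site[i] + 1L
      wr <- Wreg[s, ]
      lam_tot <- gain * pulses$amplitude_mV[i] / 75 / sum(wr)
      n_r <- rpois(3, lam_tot * wr)
      if (n_r[1L] + n_r[2L] + n_r[3L] == 0) next
      for (r in 1:3) {
        if (n_r[r] == 0) next
        by_delay <- drop(rmultinom(1L, n_r[r], EVOKED_DELAY_PROBS))
        if (by_delay[1L] > 0) {
          counts[r] <- counts[r] + by_delay[1L]
          if (is.null(landed)) landed <- matrix(0, nrow(Wreg), 3)
          landed[s, r] <- landed[s, r] + by_delay[1L]
          if (channel_mode) {
            chs <- sample_region_channels(state, s, r, by_delay[1L])
            ch <- c(ch, chs)
            lab <- c(lab, rep.int("evoked", by_delay[1L]))
          }
        }
        for (d in seq_len(horizon - 1L)) {
          nd <- by_delay[d + 1L]
          if (nd == 0) next
          tslot <- ((tick + d) %% horizon) + 1L
          state$pending_sr[tslot, s, r] <- state$pending_sr[tslot, s, r] + nd
          state$pending_any[tslot] <- TRUE
          if (channel_mode) {
            chs <- sample_region_channels(state, s, r, nd)
            state$pending_channels[[tslot]] <-
              c(state$pending_channels[[tslot]], chs)
          }
        }
      }
    }
  }
  state$last_evoked <- landed

  amp <- NULL
  if (channel_mode && length(ch)) {
    amp <- -rlnorm(length(ch), meanlog = log(20), sdlog = 0.8)
  }
  names(counts) <- REGION_NAMES
  list(counts = counts, channels = ch, amplitudes = amp, labels = lab)
}

REGION_NAMES <- c("motor1", "motor2", "sensory")

#' Collect one culture step's events as a data.frame
#' @param step result of [culture_step()] at channel resolution.
#' @param tick the tick that produced it.
#' @return data.frame `channel`, `tick`, `amplitude`, `label`.
#' @export
culture_events <- function(step, tick) {
  n <- length(step$channels)
  data.frame(channel = if (n) step$channels else integer(0),
             tick = rep.int(tick, n),
             amplitude = if (n) step$amplitudes else numeric(0),
             label = if (n) step$labels else character(0))
}

# channel attribution for evoked spikes, in proportion to the coupling;
# only ever called inside the culture stream's RNG context
sample_region_channels <- function(state, site, r, n) {
  cols <- which(state$region_index == r)
  w <- state$W[site, cols]
  cols[sample.int(length(cols), n, replace = TRUE, prob = w)] - 1L
}

#' Credit the acting motor region with the evoked spikes that drove it
#'
#' Eligibility is a stimulus-response-action coincidence trace: after
#' each decoded bin, the evoked spikes that landed in the bin are
#' credited to their stimulation sites *for the region whose activity
#' won the decode* (that is, the region that actually moved the paddle).
#' A later predictable feedback then potentiates exactly the
#' site-to-region couplings whose activity produced the successful
#' behaviour; without the action gate the trace would be symmetric
#' across motor regions and carry no directional information.
#'
#' @param state a `culture_state` environment (mutated in place).
#' @param region the acting region: 1 (motor 1, "up") or 2 (motor 2,
#'   "down"); call only when a command was issued.
#' @param tick current tick (for trace decay).
#' @return the state, invisibly.
#' @export
culture_credit <- function(state, region, tick = state$elig_tick) {
  le <- state$last_evoked
  if (is.null(le)) return(invisible(state))
  decay_elig(state, tick)
  state$elig[, region] <- state$elig[, region] + le[, region]
  invisible(state)
}

decay_elig <- function(state, tick) {
  if (tick > state$elig_tick) {
    state$elig <- state$elig *
      exp(-(tick - state$elig_tick) * state$dt / state$profile$elig_tau_s)
    state$elig_tick <- tick
  }
  invisible(state)
}

#' Apply outcome feedback to the culture's coupling
#'
#' * `predictable` (after a hit): couplings are potentiated along the
#'   current eligibility trace - the site-to-region associations that
#'   were recently active, and therefore produced the successful
#'   interception, are reinforced. The region-level increment is spread
#'   over the region's channels in proportion to the existing coupling
#'   profile (channels that fired were sampled in that proportion).
#' * `unpredictable` (after a miss): couplings receive zero-mean
#'   multiplicative noise scaled by `eta_perturb`, destabilizing the
#'   mapping that produced the failure.
#' * `silent_gap`: same perturbation with the weaker `eta_silent`.
#' * `none`: no change.
#'
#' Weights are clipped to `[0, w_max]` elementwise.
#'
#' @param state a `culture_state` environment (mutated in place).
#' @param label feedback label.
#' @param tick current tick (for eligibility decay).
#' @param scale multiplier on the update rate; used for implicit
#'   (attenuated) reinforcement, e.g. a hit under the silent condition,
#'   whose predictable sensory consequence - the rally continuing with
#'   patterned stimulation - reinforces more weakly than the explicit
#'   synchronous burst.
#' @return the state, invisibly.
#' @export
apply_feedback <- function(state, label, tick = state$elig_tick,
                           scale = 1) {
  p <- state$profile
  if (label == "none") return(invisible(state))
  if (!label %in% c("predictable", "unpredictable", "silent_gap"))
    stop("unknown feedback label: ", label)
  decay_elig(state, tick)
  if (label == "predictable") {
    tot <- sum(state$elig)
    if (scale * p$eta_potentiate > 0 && tot > 0) {
      # each hit injects a fixed mass eta_potentiate of coupling,
      # distributed over (site, region) pairs by their eligibility and
      # within a region by the existing coupling profile
      for (r in 1:3) {
        if (all(state$elig[, r] == 0)) next
        cols <- which(state$region_index == r)
        sub <- state$W[, cols, drop = FALSE]
        rs <- rowSums(sub)
        inc <- scale * p$eta_potentiate * (state$elig[, r] / tot) /
          pmax(rs, 1e-12)
        state$W[, cols] <- sub * (1 + inc)
      }
    }
  } else {
    eta <- scale * (if (label == "unpredictable") p$eta_perturb
                    else p$eta_silent)
    if (eta > 0) {
      noise <- rng_draw(state$rng,
        matrix(stats::rnorm(length(state$W)), nrow(state$W)))
      state$W <- state$W + eta * abs(state$W) * noise
    }
  }
  state$W[state$W < 0] <- 0
  state$W[state$W > p$w_max] <- p$w_max
  state$Wreg <- region_sums(state$W, state$region_index)
  invisible(state)
}

#' Render spike events as a synthetic voltage trace
#'
#' Each spike is drawn as a stereotyped biphasic waveform (1 ms,
#' negative-then-positive, peak aligned to the event sample) scaled to a
#' target signal-to-noise ratio over Gaussian background noise;
#' overlapping events sum linearly. Optional stimulation artifacts -
#' large square biphasic deflections across all channels - are rendered
#' at logged command samples so that blinding can be exercised
#' end-to-end.
#'
#' @param events data.frame with `channel` (0-based) and `sample`.
#' @param n_samples,n_channels trace dimensions.
#' @param noise_sd background noise standard deviation, microvolts.
#' @param snr spike peak amplitude as a multiple of `noise_sd`.
#' @param spike_uV absolute spike peak amplitude, microvolts; overrides
#'   `snr * noise_sd` (and is the amplitude used on a noiseless trace).
#' @param stim_samples samples at which stimulation artifacts occur.
#' @param artifact_uV artifact amplitude, microvolts (80 mV default).
#' @param rng an [rng_stream()] for the background noise.
#' @return numeric matrix (samples x channels), microvolts.
#' @export
synth_voltage <- function(events, n_samples, n_channels, noise_sd = 3,
                          snr = 8, spike_uV = NULL,
                          stim_samples = integer(0),
                          artifact_uV = 80000, rng = rng_stream(0)) {
  v <- if (noise_sd > 0) {
    rng_eval(rng, matrix(stats::rnorm(n_samples * n_channels, 0, noise_sd),
                         n_samples, n_channels))
  } else matrix(0, n_samples, n_channels)
  amp <- spike_uV %||% (if (noise_sd > 0) snr * noise_sd else snr)
  wf <- -sin(pi * (0:19) / 10) * amp   # peak at index 5
  if (NROW(events) > 0) {
    if (is.unsorted(events$sample)) stop("events must be sorted by sample")
    for (i in seq_len(nrow(events))) {
      s0 <- events$sample[i] - 5L
      kk <- which(s0 + 0:19 >= 0 & s0 + 0:19 < n_samples)
      v[s0 + kk, events$channel[i] + 1L] <-
        v[s0 + kk, events$channel[i] + 1L] + wf[kk]
    }
  }
  for (s in stim_samples) {
    kk <- s + 0:9
    kk <- kk[kk >= 0 & kk < n_samples]
    v[kk + 1L, ] <- v[kk + 1L, ] +
      artifact_uV * rep(c(1, -1), each = 5)[seq_along(kk)]
  }
  v
}
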