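#' Write a session's logs to a directory
#'
#' Produces the on-disk record of a session: `manifest.json` (the full
#' configuration snapshot plus run bookkeeping), `rallies.csv`,
#' `events.csv`, `stim_log.csv`, `bandit_trace.csv` (when the bandit
#' ran), and - for channel-resolution sessions - the binary spike log
#' `spikes.bin` with its `spikes.json` sidecar. Identical (config, seed)
#' pairs produce byte-identical logs.
#'
#' @param session a `pong_session` from [run_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- session$config
  manifest <- list(
    condition = cfg$condition, seed = cfg$seed, profile = cfg$profile,
    layout_id = cfg$layout_id, bandit = cfg$bandit,
    bandit_gamma = cfg$bandit_gamma, duration_min = cfg$duration_min,
    resolution = cfg$resolution, exclude_first_s = cfg$exclude_first_s,
    profile_options = cfg$profile_options,
    game = unclass(cfg$game),
    paddle_distance = session$paddle_distance,
    n_ticks = session$n_ticks)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(session$rallies, file.path(dir, "rallies.csv"),
                   row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(session$stim_log, file.path(dir, "stim_log.csv"),
                   row.names = FALSE)
  if (!is.null(session$bandit_trace))
    utils::write.csv(session$bandit_trace, file.path(dir, "bandit_trace.csv"),
                     row.names = FALSE)
  if (!is.null(session$spikes)) write_spike_log(session$spikes, dir)
  invisible(dir)
}

#' Binary spike log
#'
#' Spike events are stored as little-endian records of 10 bytes - uint32
#' sample index, uint16 channel, float32 amplitude (microvolts) - with a
#' JSON sidecar recording the sampling rate, channel count, record count
#' and detector settings. The record count makes truncation detectable.
#'
#' @param spikes data.frame with `sample`, `channel`, `amplitude`.
#' @param dir directory for `spikes.bin` / `spikes.json`.
#' @param fs sampling rate, Hz.
#' @return invisibly, the path of the binary file.
#' @export
write_spike_log <- function(spikes, dir, fs = 20000) {
  path <- file.path(dir, "spikes.bin")
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq(1, NROW(spikes), by = 65536)) {
    jj <- i:min(i + 65535, NROW(spikes))
    raw <- writeBin(as.integer(spikes$sample[jj]), raw(), size = 4,
                    endian = "little")
    dim(raw) <- c(4L, length(jj))
    raw2 <- writeBin(as.integer(spikes$channel[jj]), raw(), size = 4,
                     endian = "little")
    dim(raw2) <- c(4L, length(jj))
    raw3 <- writeBin(as.numeric(spikes$amplitude[jj]), raw(), size = 4,
                     endian = "little")
    dim(raw3) <- c(4L, length(jj))
    rec <- rbind(raw, raw2[1:2, , drop = FALSE], raw3)
    writeBin(as.vector(rec), con)
  }
  jsonlite::write_json(
    list(sampling_rate_hz = fs, n_channels = 1024L,
         n_records = NROW(spikes), record_bytes = 10L,
         fields = c("sample:uint32", "channel:uint16", "amplitude:float32"),
         endianness = "little"),
    file.path(dir, "spikes.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname write_spike_log
#' @param dir directory containing `spikes.bin` and `spikes.json`.
#' @export
read_spike_log <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spikes.json"),
                              simplifyVector = TRUE)
  path <- file.path(dir, "spikes.bin")
  expected <- meta$n_records * meta$record_bytes
  if (file.info(path)$size != expected)
    stop("spike log integrity error: expected ", expected, " bytes, found ",
         file.info(path)$size)
  raw <- readBin(path, "raw", n = expected)
  dim(raw) <- c(10L, meta$n_records)
  sample <- readBin(as.vector(raw[1:4, , drop = FALSE]), "integer",
                    n = meta$n_records, size = 4, endian = "little")
  channel <- readBin(as.vector(raw[5:6, , drop = FALSE]), "integer",
                     n = meta$n_records, size = 2, endian = "little",
                     signed = FALSE)
  amplitude <- readBin(as.vector(raw[7:10, , drop = FALSE]), "numeric",
                       n = meta$n_records, size = 4, endian = "little")
  data.frame(sample = sample, channel = channel, amplitude = amplitude)
}

#' Read a session back from its logs
#'
#' @param dir directory written by [write_session()].
#' @return a `pong_session` reconstructed from the logs (ground-truth
#'   spike labels, which exist only in memory, are not restored).
#' @export
read_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  game <- do.call(game_config, man$game)
  cfg <- session_config(condition = man$condition, seed = man$seed,
                        profile = man$profile, layout_id = man$layout_id,
                        bandit = man$bandit, bandit_gamma = man$bandit_gamma,
                        duration_min = man$duration_min,
                        resolution = man$resolution, game = game,
                        profile_options = as.list(man$profile_options),
                        exclude_first_s = man$exclude_first_s)
  rallies <- utils::read.csv(file.path(dir, "rallies.csv"))
  events <- utils::read.csv(file.path(dir, "events.csv"))
  stim_log <- utils::read.csv(file.path(dir, "stim_log.csv"))
  bt_path <- file.path(dir, "bandit_trace.csv")
  bandit_trace <- if (file.exists(bt_path)) utils::read.csv(bt_path) else NULL
  spikes <- NULL
  if (file.exists(file.path(dir, "spikes.bin"))) {
    spikes <- read_spike_log(dir)
    spt <- as.integer(round(20000 / game$ticks_per_second))
    spikes$tick <- spikes$sample %/% spt
    spikes <- spikes[, c("channel", "tick", "sample", "amplitude")]
  }
  structure(list(config = cfg, rallies = rallies, events = events,
                 stim_log = stim_log, spikes = spikes,
                 bandit_trace = bandit_trace,
                 summary = summarize_rallies(rallies, man$paddle_distance,
                                             game$long_rally_threshold),
                 paddle_distance = man$paddle_distance,
                 n_ticks = man$n_ticks),
            class = "pong_session")
}

#' Per-electrode activity image on the 32 x 32 grid
#'
#' @param events spike events with `channel` (0-based).
#' @param layout an [electrode_layout()].
#' @return 32 x 32 matrix of spike counts (row 1 = bottom row).
#' @export
activity_image <- function(events, layout) {
  img <- matrix(0, 32, 32)
  if (NROW(events)) {
    ch <- layout$channels
    idx <- cbind(ch$row[events$channel + 1L] + 1L,
                 ch$col[events$channel + 1L] + 1L)
    for (i in seq_len(nrow(idx))) img[idx[i, 1], idx[i, 2]] <-
        img[idx[i, 1], idx[i, 2]] + 1
  }
  img
}

region_count_series <- function(events, layout, t_start, t_end, bin_s) {
  n_bin <- floor((t_end - t_start) / bin_s + 1e-9)
  reg <- layout$channels$region[events$channel + 1L]
  keep <- events$time_s >= t_start & events$time_s < t_start + n_bin * bin_s
  bin <- floor((events$time_s[keep] - t_start) / bin_s)
  out <- list()
  for (r in c("sensory", "motor1", "motor2")) {
    out[[r]] <- as.numeric(table(factor(bin[reg[keep] == r],
                                        levels = 0:(n_bin - 1L))))
  }
  out
}

#' Compute the per-session analysis report
#'
#' Assembles the session-level statistics into one row: gameplay metrics
#' (average rally length, aces, long rallies, paddle distance), mean
#' clustered entropy, spike-normalized pre/post feedback entropy,
#' centre-of-activity plasticity (when a matched rest session is
#' supplied), the four DCT asymmetry modes, the lagged sensory-to-motor
#' cross-correlations, and the exclusive motor-event fraction. Raster
#' statistics require a channel-resolution session and are `NA`
#' otherwise; the first `exclude_first_s` seconds of spiking are
#' excluded from all electrophysiological statistics.
#'
#' @param session a `pong_session`.
#' @param rest_session optional matched rest-condition `pong_session`
#'   (channel resolution) for the plasticity score.
#' @param exclude_first_s override of the config's exclusion window.
#' @return a one-row data.frame; analysis parameters are attached as the
#'   `"params"` attribute.
#' @export
analyze_session <- function(session, rest_session = NULL,
                            exclude_first_s = NULL) {
  cfg <- session$config
  excl <- exclude_first_s %||% cfg$exclude_first_s
  tps <- cfg$game$ticks_per_second
  duration_s <- cfg$duration_min * 60
  s <- session$summary

  out <- data.frame(
    condition = cfg$condition, profile = cfg$profile, seed = cfg$seed,
    avg_rally_length = s$avg_rally_length, aces = s$aces,
    long_rallies = s$long_rallies, paddle_distance = s$paddle_distance,
    mean_entropy = NA_real_, normalized_entropy_pre = NA_real_,
    normalized_entropy_post = NA_real_,
    ca_plasticity_gameplay = NA_real_, ca_plasticity_rest = NA_real_,
    dct_01 = NA_real_, dct_02 = NA_real_, dct_10 = NA_real_,
    dct_20 = NA_real_, xcorr_m1 = NA_real_, xcorr_m2 = NA_real_,
    exclusive_fraction = NA_real_)

  if (!is.null(session$spikes) && nrow(session$spikes) > 0) {
    layout <- electrode_layout(cfg$layout_id)
    ev <- session$spikes
    ev$time_s <- ev$tick / tps
    scheme <- cluster_scheme()

    ce <- clustered_entropy(ev, scheme, excl, duration_s)
    out$mean_entropy <- ce$mean

    miss_ticks <- session$events$tick[session$events$kind == "miss"]
    if (length(miss_ticks) && cfg$condition %in% c("stimulus", "silent")) {
      pp <- pre_post_feedback_entropy(ev, miss_ticks / tps, scheme,
                                      excl, duration_s)
      if (nrow(pp)) {
        out$normalized_entropy_pre <- mean(pp$pre_norm)
        out$normalized_entropy_post <- mean(pp$post_norm)
      }
    }

    img <- activity_image(ev[ev$time_s >= excl, , drop = FALSE], layout)
    if (mean(img) > 0) {
      dm <- dct_modes(img)
      pick <- function(u, v) dm$abs_norm[dm$u == u & dm$v == v]
      out$dct_01 <- pick(0, 1); out$dct_02 <- pick(0, 2)
      out$dct_10 <- pick(1, 0); out$dct_20 <- pick(2, 0)
    }

    rc <- region_count_series(ev, layout, excl, duration_s, 0.1)
    out$xcorr_m1 <- suppressWarnings(
      lagged_cross_correlation(rc$sensory, rc$motor1))
    out$xcorr_m2 <- suppressWarnings(
      lagged_cross_correlation(rc$sensory, rc$motor2))

    out$exclusive_fraction <-
      exclusive_motor_events(ev, layout, excl, duration_s)$fraction

    if (!is.null(rest_session) && !is.null(rest_session$spikes)) {
      rev_ <- rest_session$spikes
      rev_$time_s <- rev_$tick / tps
      coords <- as.matrix(layout$channels[, c("col", "row")])
      ps <- try(plasticity_score(
        ev, rev_, coords,
        gameplay_span = c(excl, duration_s),
        rest_span = c(rest_session$config$exclude_first_s,
                      rest_session$config$duration_min * 60)),
        silent = TRUE)
      if (!inherits(ps, "try-error")) {
        out$ca_plasticity_gameplay <- ps$gameplay
        out$ca_plasticity_rest <- ps$rest
      }
    }
  }
  attr(out, "params") <- list(exclude_first_s = excl,
                              entropy_window_s = 0.1,
                              prepost_window_s = 4,
                              ca_bin_s = 1, ca_window_s = 300,
                              xcorr_bin_s = 0.1, xcorr_lag_bins = 1,
                              exclusive_bin_s = 1,
                              exclusive_amplitude_uV = -5)
  out
}

#' Express gameplay metrics as percent change over matched rest
#'
#' @param gameplay,rest one-row analysis reports ([analyze_session()])
#'   or gameplay summaries for the same culture and seed family.
#' @return named numeric vector of percent changes; metrics whose rest
#'   value is zero (or missing) are omitted with a warning.
#' @export
rest_normalize <- function(gameplay, rest) {
  gv <- unlist(numeric_metrics(gameplay))
  rv <- unlist(numeric_metrics(rest))
  common <- intersect(names(gv), names(rv))
  gv <- gv[common]; rv <- rv[common]
  ok <- is.finite(gv) & is.finite(rv) & rv != 0
  if (any(!ok))
    warning("metrics omitted (zero or missing rest value): ",
            paste(common[!ok], collapse = ", "))
  100 * (gv[ok] - rv[ok]) / rv[ok]
}

numeric_metrics <- function(x) {
  if (inherits(x, "gameplay_summary"))
    x <- data.frame(avg_rally_length = x$avg_rally_length, aces = x$aces,
                    long_rallies = x$long_rallies,
                    paddle_distance = x$paddle_distance)
  x[vapply(x, is.numeric, logical(1))]
}

#' Replay a logged session's analysis
#'
#' Re-reads the logs and recomputes the analysis report; when a stored
#' report (`report.csv`) exists, verifies that the recomputation
#' reproduces it exactly. Corrupt or truncated logs raise an integrity
#' error rather than a silent partial analysis.
#'
#' @param dir session directory ([write_session()]).
#' @param rest_dir optional matched rest-session directory.
#' @return the recomputed report.
#' @export
replay_session <- function(dir, rest_dir = NULL) {
  session <- read_session(dir)
  rest <- if (!is.null(rest_dir)) read_session(rest_dir) else NULL
  report <- analyze_session(session, rest)
  stored <- file.path(dir, "report.csv")
  if (file.exists(stored)) {
    prev <- utils::read.csv(stored)
    num <- vapply(report, is.numeric, logical(1))
    same <- all(vapply(names(report)[num], function(nm) {
      a <- report[[nm]]; b <- prev[[nm]]
      (is.na(a) && is.na(b)) || isTRUE(all.equal(a, b, tolerance = 1e-12))
    }, logical(1)))
    if (!same) stop("replay mismatch: recomputed report differs from stored")
  }
  report
}

#' Run the multi-condition experiment harness
#'
#' Runs `conditions x days x sessions_per_day` sessions with seeds
#' derived deterministically from the batch seed and returns a tidy
#' long-format table of per-session performance (gameplay summary plus
#' the T1/T2 contrast).
#'
#' @param seed batch seed.
#' @param conditions feedback conditions to run.
#' @param days,sessions_per_day experiment grid (3 x 3 by default).
#' @param profile culture profile name.
#' @param duration_min session duration.
#' @param ... further arguments passed to [session_config()].
#' @return data.frame with one row per session.
#' @export
run_experiment <- function(seed, conditions = c("stimulus", "silent",
                                                "no_feedback"),
                           days = 3, sessions_per_day = 3,
                           profile = "learner_human", duration_min = 20,
                           ...) {
  rows <- list()
  k <- 0L
  for (cond in conditions) for (d in seq_len(days))
    for (ses in seq_len(sessions_per_day)) {
      k <- k + 1L
      s_seed <- (as.double(seed) * 7919 + k * 104729) %% 2147483647
      s <- run_session(session_config(cond, seed = s_seed,
                                      profile = profile,
                                      duration_min = duration_min, ...))
      tp <- timepoint_performance(s)
      rows[[k]] <- data.frame(
        condition = cond, day = d, session = ses, seed = s_seed,
        n_rallies = s$summary$n_rallies,
        avg_rally_length = s$summary$avg_rally_length,
        aces = s$summary$aces, long_rallies = s$summary$long_rallies,
        paddle_distance = s$summary$paddle_distance,
        t1 = tp$t1, t2 = tp$t2, t2_minus_t1 = tp$diff)
    }
  do.call(rbind, rows)
}
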