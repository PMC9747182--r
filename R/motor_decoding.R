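#' Motor-electrode layout presets
#'
#' The 1024 routed channels are arranged on a 32 x 32 logical grid,
#' indexed column-major (channel = 32*col + row; row 0 is the bottom of
#' the array, matching the bottom-left reference corner used by the
#' centre-of-activity statistic). A central band of 626 channels forms
#' the sensory region, which embeds the 8 stimulation sites; the two
#' flanking bands (199 channels each) form four motor sub-blocks (left
#' upper/lower, right upper/lower) that the five preset configurations
#' assign to motor region 1 ("up") and motor region 2 ("down") in
#' counterbalanced patterns:
#'
#' * config 0 - upper blocks vs lower blocks (the simple layout),
#' * config 1 - left band vs right band,
#' * config 2 - diagonal (left-upper + right-lower vs the rest),
#' * config 3 - anti-diagonal (left-lower + right-upper vs the rest);
#'   the default configuration,
#' * config 4 - row-interleaved stripes within each band.
#'
#' The stimulation sites are 8 sensory-region channels in the middle
#' column at evenly spaced heights, ordered bottom-to-top as sites 0..7.
#'
#' @param layout_id integer 0..4.
#' @return an object of class `electrode_layout`: list with `channels`
#'   (data.frame `channel`, `row`, `col`, `region`), `stim_sites`
#'   (8 channel indices), `layout_id`, and `region_channels` (list of
#'   0-based channel indices per region).
#' @export
electrode_layout <- function(layout_id = 3L) {
  layout_id <- as.integer(layout_id)
  if (!layout_id %in% 0:4) stop("layout_id must be in 0..4")
  channel <- 0:1023
  row <- channel %% 32L
  col <- channel %/% 32L

  left <- channel < 199L          # left flank, 199 channels
  right <- channel >= 825L        # right flank, 199 channels
  sensory <- !(left | right)      # central 626 channels
  upper <- row >= 16L

  m1 <- switch(as.character(layout_id),
    "0" = (left | right) & upper,
    "1" = left,
    "2" = (left & upper) | (right & !upper),
    "3" = (left & !upper) | (right & upper),
    "4" = (left | right) & (row %% 2L == 0L))
  region <- ifelse(sensory, "sensory", ifelse(m1, "motor1", "motor2"))

  stim_rows <- as.integer(seq(2, 30, by = 4))
  stim_sites <- 32L * 16L + stim_rows   # middle column, bottom-to-top
  stopifnot(all(region[stim_sites + 1L] == "sensory"))

  channels <- data.frame(channel = channel, row = row, col = col,
                         region = region)
  validate_layout(structure(list(
    channels = channels,
    stim_sites = stim_sites,
    layout_id = layout_id,
    region_channels = split(channel, region)
  ), class = "electrode_layout"))
}

validate_layout <- function(layout) {
  ch <- layout$channels
  if (nrow(ch) != 1024L) stop("layout must route exactly 1024 channels")
  if (sum(ch$region == "sensory") != 626L)
    stop("sensory region must contain 626 channels")
  if (length(layout$stim_sites) != 8L)
    stop("layout must define 8 stimulation sites")
  if (!all(ch$region[layout$stim_sites + 1L] == "sensory"))
    stop("stimulation sites must lie inside the sensory region")
  n1 <- sum(ch$region == "motor1"); n2 <- sum(ch$region == "motor2")
  if (n1 == 0L || n2 == 0L) stop("motor regions must be non-empty")
  layout
}

#' Write / read a layout as JSON
#'
#' @param layout an [electrode_layout()].
#' @param path file path.
#' @return `read_layout` returns a validated `electrode_layout`.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(layout_id = layout$layout_id,
                            channels = layout$channels,
                            stim_sites = layout$stim_sites),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- as.data.frame(j$channels)
  validate_layout(structure(list(
    channels = channels,
    stim_sites = as.integer(j$stim_sites),
    layout_id = as.integer(j$layout_id),
    region_channels = split(channels$channel, channels$region)
  ), class = "electrode_layout"))
}

#' Count spikes per region in one 10 ms bin
#'
#' @param events data.frame with `channel` (0-based) and `sample` columns.
#' @param layout an [electrode_layout()].
#' @param bin_start first 20 kHz sample of the bin.
#' @param bin_samples bin width in samples (200 = 10 ms).
#' @return named numeric vector with counts for `motor1`, `motor2`,
#'   `sensory`.
#' @export
bin_spikes <- function(events, layout, bin_start, bin_samples = 200L) {
  if (NROW(events) > 0 &&
      any(events$sample < bin_start | events$sample >= bin_start + bin_samples))
    stop("events outside the requested bin")
  out <- c(motor1 = 0, motor2 = 0, sensory = 0)
  if (NROW(events) > 0) {
    reg <- layout$channels$region[events$channel + 1L]
    t <- table(factor(reg, levels = names(out)))
    out[] <- as.numeric(t)
  }
  out
}

#' Initialize the activity-gain state
#'
#' Each motor region's firing rate is tracked by an exponential moving
#' average and compared to a 20 Hz target: a region running above target
#' gets a correction factor above 1, below target a factor below 1.
#' Drives are compared after dividing the instantaneous count by the
#' region's factor, which equalizes chronically asymmetric regions (a
#' region twice as active as target contributes half weight per spike).
#' The factor is clamped so silent regions cannot blow up the division.
#'
#' @param target_rate target rate, Hz.
#' @param tau EMA time constant, seconds.
#' @param clamp length-2 numeric, correction-factor bounds.
#' @param init_rate initial smoothed rate, Hz (defaults to target).
#' @return an object of class `gain_state`.
#' @export
gain_state <- function(target_rate = 20, tau = 10, clamp = c(0.1, 10),
                       init_rate = target_rate) {
  structure(list(rate = c(motor1 = init_rate, motor2 = init_rate),
                 target_rate = target_rate, tau = tau, clamp = clamp),
            class = "gain_state")
}

#' Update the gain state with one bin of counts
#'
#' @param state a [gain_state()].
#' @param counts named vector with `motor1`, `motor2` spike counts.
#' @param dt bin duration, seconds (0.01).
#' @return updated `gain_state`.
#' @export
update_gain <- function(state, counts, dt = 0.01) {
  a <- dt / state$tau
  inst <- counts[c("motor1", "motor2")] / dt
  state$rate <- (1 - a) * state$rate + a * inst
  state
}

#' Correction factors from the current gain state
#' @param state a [gain_state()].
#' @return named vector of clamped correction factors.
#' @export
gain_factors <- function(state) {
  pmin(pmax(state$rate / state$target_rate, state$clamp[1]), state$clamp[2])
}

#' Decode one bin of motor counts into a paddle command
#'
#' The decision is a bare gain-normalized two-way comparison: the region
#' with the higher corrected drive moves the paddle in its direction
#' (motor region 1 is "up", motor region 2 "down"); equal drives leave
#' the paddle still. No other weighting or learning is applied on the
#' decoding side.
#'
#' @param counts named vector with `motor1`, `motor2` spike counts.
#' @param state a [gain_state()] already updated for this bin.
#' @return list with `direction` (`"up"`, `"down"`, `"none"`) and
#'   `drives` (the corrected drives).
#' @export
decode_motor <- function(counts, state) {
  f <- gain_factors(state)
  drives <- c(motor1 = unname(counts["motor1"] / f["motor1"]),
              motor2 = unname(counts["motor2"] / f["motor2"]))
  direction <- if (drives[1] > drives[2]) "up"
               else if (drives[2] > drives[1]) "down" else "none"
  list(direction = direction, drives = drives)
}
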