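#' Bessel filter designs used by the spike detector
#'
#' The detector front-end is a 2nd-order high-pass Bessel filter with
#' 100 Hz cutoff run at 20 kHz, followed (after rectification) by a
#' 1st-order low-pass Bessel smoother with 1 Hz cutoff that tracks the
#' noise envelope. Both are designed from the analog Bessel prototype
#' (poles of `s^2 + 3s + 3` for the 2nd order, `s + 1` for the 1st),
#' magnitude-normalized so the cutoff is the -3 dB point, then converted
#' with [signal::sftrans()] and discretized by the bilinear transform
#' ([signal::bilinear()]) with frequency pre-warping at the cutoff.
#'
#' @param fc cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
bessel_highpass2 <- function(fc = 100, fs = 20000) {
  bessel_design(order = 2L, fc = fc, fs = fs, type = "high")
}

#' @rdname bessel_highpass2
#' @export
bessel_lowpass1 <- function(fc = 1, fs = 20000) {
  bessel_design(order = 1L, fc = fc, fs = fs, type = "low")
}

bessel_design <- function(order, fc, fs, type) {
  if (order == 2L) {
    # poles of the reversed Bessel polynomial s^2 + 3 s + 3, scaled so the
    # -3 dB magnitude point sits at omega = 1
    w3 <- sqrt((-3 + sqrt(45)) / 2)
    poles <- c(complex(real = -1.5, imaginary = sqrt(3) / 2),
               complex(real = -1.5, imaginary = -sqrt(3) / 2)) / w3
    gain <- 3 / w3^2
  } else if (order == 1L) {
    poles <- as.complex(-1)
    gain <- 1
  } else stop("only orders 1 and 2 are provided")
  proto <- signal::Zpg(zero = numeric(0), pole = poles, gain = gain)
  W <- tan(pi * fc / fs)  # bilinear pre-warp (T = 2 convention)
  st <- signal::sftrans(proto, W = W, stop = (type == "high"))
  dt <- signal::bilinear(st, T = 2)
  ar <- signal::as.Arma(dt)
  b <- Re(ar$b); a <- Re(ar$a)
  list(b = b / a[1], a = a / a[1])
}

#' Streaming IIR filter state
#'
#' Wraps a designed filter with enough input/output history that a trace
#' can be processed in arbitrary chunks with results identical to batch
#' filtering: the filters are causal and stateful, as in the real-time
#' detector.
#'
#' @param filt list with `b`, `a` as from [bessel_highpass2()].
#' @param n_channels number of parallel channels.
#' @return an `iir_state` object.
#' @export
iir_init <- function(filt, n_channels = 1L) {
  ord <- length(filt$a) - 1L
  structure(list(b = filt$b, a = filt$a, order = ord,
                 x_prev = matrix(0, ord, n_channels),
                 y_prev = matrix(0, ord, n_channels)),
            class = "iir_state")
}

#' Filter one chunk of samples, advancing the stream state
#'
#' @param state an [iir_init()] state.
#' @param x numeric matrix (samples x channels) or vector.
#' @return list with `y` (filtered, same shape) and `state`.
#' @export
iir_step <- function(state, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(state$x_prev))
  if (any(!is.finite(x))) stop("non-finite input to IIR filter")
  ord <- state$order
  y <- x
  for (ch in seq_len(ncol(x))) {
    xa <- c(state$x_prev[, ch], x[, ch])
    u <- stats::filter(xa, state$b, method = "convolution", sides = 1)
    u <- as.numeric(u)[-seq_len(ord)]
    if (ord > 0) {
      yv <- stats::filter(u, -state$a[-1], method = "recursive",
                          init = rev(state$y_prev[, ch]))
    } else yv <- u
    y[, ch] <- as.numeric(yv)
    # history carried via the augmented vectors so chunks shorter than
    # the filter order stream correctly
    ya <- c(state$y_prev[, ch], y[, ch])
    n_a <- length(xa)
    state$x_prev[, ch] <- xa[seq.int(n_a - ord + 1L, n_a)]
    state$y_prev[, ch] <- ya[seq.int(n_a - ord + 1L, n_a)]
  }
  list(y = y, state = state)
}

#' Evaluate the magnitude response of a digital filter
#' @param filt list with `b`, `a`.
#' @param f frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return |H(f)|.
#' @export
filter_gain <- function(filt, f, fs = 20000) {
  z <- exp(-1i * 2 * pi * f / fs)
  abs(polyval_c(filt$b, z) / polyval_c(filt$a, z))
}

polyval_c <- function(p, z) {
  acc <- 0 + 0i
  for (k in seq_along(p)) acc <- acc * z + p[k]
  acc
}

#' Detect spikes with a noise-proportional threshold
#'
#' The high-passed trace is rectified and smoothed by the 1 Hz envelope
#' filter; a spike event is emitted whenever `|filtered|` crosses
#' `k * envelope` (k = 6 by default, the "six sigma" detector setting),
#' with the event placed at the peak of each supra-threshold excursion
#' and its signed amplitude recorded. A per-channel refractory hold
#' suppresses re-triggering, and no events are emitted during the
#' envelope warm-up (the 1 Hz smoother needs time to settle). Because the
#' threshold is proportional to the tracked envelope, the detector is
#' self-calibrating: rescaling the input voltage leaves event times
#' unchanged.
#'
#' @param filtered numeric matrix (samples x channels), high-passed trace.
#' @param envelope numeric matrix, smoothed |filtered| (same shape).
#' @param k threshold multiplier.
#' @param refractory_samples per-channel hold after an event (20 = 1 ms).
#' @param warmup_samples samples at the start that emit no events
#'   (default 2 s).
#' @param sample_offset index of the first row in stream coordinates.
#' @return data.frame `channel` (0-based), `sample`, `amplitude`
#'   (signed, same units as the input), sorted by sample.
#' @export
detect_spikes <- function(filtered, envelope, k = 6,
                          refractory_samples = 20L,
                          warmup_samples = 40000L,
                          sample_offset = 0L) {
  stopifnot(identical(dim(filtered), dim(envelope)))
  out <- vector("list", ncol(filtered))
  for (ch in seq_len(ncol(filtered))) {
    y <- filtered[, ch]
    above <- abs(y) > k * envelope[, ch]
    above[seq_len(min(length(above), warmup_samples - sample_offset))] <- FALSE
    idx <- which(above)
    if (!length(idx)) next
    run_id <- cumsum(c(1L, diff(idx) > 1L))
    peaks <- vapply(split(idx, run_id),
                    function(ii) ii[which.max(abs(y[ii]))], integer(1))
    keep <- logical(length(peaks))
    last <- -Inf
    for (j in seq_along(peaks)) {
      if (peaks[j] - last >= refractory_samples) { keep[j] <- TRUE; last <- peaks[j] }
    }
    peaks <- peaks[keep]
    out[[ch]] <- data.frame(channel = ch - 1L,
                            sample = peaks - 1L + sample_offset,
                            amplitude = y[peaks])
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) ev <- data.frame(channel = integer(0), sample = integer(0),
                                    amplitude = numeric(0))
  ev <- ev[order(ev$sample, ev$channel), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Run the full detection chain on a voltage trace
#'
#' Convenience wrapper: 100 Hz Bessel high-pass, rectified 1 Hz Bessel
#' envelope, proportional-threshold detection.
#'
#' @param voltage numeric matrix (samples x channels), microvolts.
#' @param fs sampling rate, Hz.
#' @param k threshold multiplier.
#' @param warmup_s envelope warm-up, seconds.
#' @return events data.frame as from [detect_spikes()].
#' @export
spike_detect_chain <- function(voltage, fs = 20000, k = 6, warmup_s = 2) {
  if (is.null(dim(voltage))) voltage <- matrix(voltage, ncol = 1)
  hp <- iir_step(iir_init(bessel_highpass2(100, fs), ncol(voltage)), voltage)
  env <- iir_step(iir_init(bessel_lowpass1(1, fs), ncol(voltage)), abs(hp$y))
  detect_spikes(hp$y, env$y, k = k, warmup_samples = as.integer(warmup_s * fs))
}

#' Blind spike readout around stimulation commands
#'
#' Command-count blinding: every event on any channel whose sample lies
#' in `[command, command + window)` for a logged stimulation command is
#' dropped, so stimulation artifacts are never counted as neural
#' activity. An optional legacy consensus mode instead drops whole frames
#' in which more than 15 simultaneous large events (|amplitude| > 75 mV)
#' are detected; it is retained because it illustrates the failure mode
#' that motivated command-count blinding.
#'
#' @param events data.frame with `sample` (and `amplitude`, microvolts,
#'   for consensus mode), sorted by sample.
#' @param stim_samples sorted vector of stimulation-command samples
#'   (ignored in consensus mode).
#' @param window_samples blinding window length (default 100 = 5 ms).
#' @param mode `"command"` or `"consensus"`.
#' @param consensus_count frames with more than this many large events
#'   are blinded (15).
#' @param consensus_amplitude_mV large-event threshold, millivolts (75).
#' @return the surviving events, same columns.
#' @export
apply_blinding <- function(events, stim_samples, window_samples = 100L,
                           mode = c("command", "consensus"),
                           consensus_count = 15L,
                           consensus_amplitude_mV = 75) {
  mode <- match.arg(mode)
  if (NROW(events) == 0) return(events)
  if (mode == "command") {
    if (length(stim_samples) == 0) return(events)
    if (is.unsorted(stim_samples)) stop("stimulation log must be sorted")
    pos <- findInterval(events$sample, stim_samples)
    blocked <- pos > 0 &
      (events$sample - stim_samples[pmax(pos, 1L)]) < window_samples
    events[!blocked, , drop = FALSE]
  } else {
    big <- abs(events$amplitude) > consensus_amplitude_mV * 1000
    per_frame <- table(events$sample[big])
    bad <- as.numeric(names(per_frame))[per_frame > consensus_count]
    events[!(events$sample %in% bad), , drop = FALSE]
  }
}
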