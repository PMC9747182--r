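#' Binary entropy of a Bernoulli probability
#'
#' `H_b(p) = -p log2(p) - (1-p) log2(1-p)` shannons, with the convention
#' `0 log2 0 = 0`.
#'
#' @param p probability in `[0, 1]`; vectorized.
#' @return entropy in shannons, in `[0, 1]`.
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Cluster scheme: 18 rectangular blocks of 50 electrodes
#'
#' Tiles the 32 x 32 channel grid with 18 rectangular clusters of 50
#' neighbouring electrodes each (blocks of 10 rows x 5 columns over rows
#' and columns 0..29), covering 900 of the 1024 routed channels. The
#' exact rectangles are a configuration choice of the simulator; only
#' the counts (18 clusters x 50 electrodes, disjoint) are pinned.
#'
#' @return list of 18 integer vectors of 0-based channel indices.
#' @export
cluster_scheme <- function() {
  clusters <- vector("list", 18L)
  k <- 0L
  for (cb in 0:5) {          # 6 column blocks of 5 columns
    for (rb in 0:2) {        # 3 row blocks of 10 rows
      k <- k + 1L
      cols <- cb * 5L + 0:4
      rows <- rb * 10L + 0:9
      clusters[[k]] <- as.integer(outer(rows, cols * 32L, `+`))
    }
  }
  stopifnot(length(clusters) == 18L,
            all(lengths(clusters) == 50L),
            !anyDuplicated(unlist(clusters)))
  clusters
}

#' Clustered binary entropy of a spike raster
#'
#' For every 100 ms window and every cluster, `p` is the fraction of the
#' cluster's 50 electrodes that fired at least once in the window; the
#' window's local entropy is `H_b(p)`. Returns the full series and its
#' mean over time and clusters.
#'
#' @param events data.frame with `channel` (0-based) and `time_s`.
#' @param scheme a [cluster_scheme()].
#' @param t_start,t_end analysis span, seconds.
#' @param window_s window length (0.1 s).
#' @return list with `series` (windows x clusters matrix of entropies),
#'   `p` (the occupancy fractions), `window_spikes` (total spikes per
#'   window over clustered channels), and `mean`.
#' @export
clustered_entropy <- function(events, scheme, t_start, t_end,
                              window_s = 0.1) {
  n_win <- floor((t_end - t_start) / window_s + 1e-9)
  if (n_win < 1) stop("analysis span shorter than one window")
  n_cl <- length(scheme)
  cl_of <- rep(NA_integer_, 1024L)
  for (k in seq_len(n_cl)) cl_of[scheme[[k]] + 1L] <- k

  keep <- events$time_s >= t_start & events$time_s < t_start + n_win * window_s
  ev <- events[keep, , drop = FALSE]
  win <- floor((ev$time_s - t_start) / window_s)
  cl <- cl_of[ev$channel + 1L]
  ok <- !is.na(cl)

  p <- matrix(0, n_win, n_cl)
  spikes <- numeric(n_win)
  if (any(ok)) {
    # distinct (window, cluster, channel) triples -> occupied electrodes
    key <- (win[ok] * 1024 + ev$channel[ok])
    first <- !duplicated(key)
    occ <- table(factor(win[ok][first], levels = 0:(n_win - 1L)),
                 factor(cl[ok][first], levels = seq_len(n_cl)))
    p[] <- as.numeric(occ) / 50
    sp <- table(factor(win[ok], levels = 0:(n_win - 1L)))
    spikes <- as.numeric(sp)
  }
  series <- binary_entropy(p)
  list(series = series, p = p, window_spikes = spikes,
       mean = mean(series))
}

#' Normalize entropy by spike counts
#'
#' Divides each entropy value by the total spike count over the same
#' windows/regions; windows with zero spikes yield 0 by convention.
#'
#' @param entropy numeric vector of (mean) entropies.
#' @param spike_counts matching total spike counts.
#' @return normalized entropies.
#' @export
normalized_entropy <- function(entropy, spike_counts) {
  if (length(entropy) != length(spike_counts))
    stop("entropy and spike_counts must be aligned")
  ifelse(spike_counts > 0, entropy / spike_counts, 0)
}

#' Mean entropy before vs after feedback events
#'
#' For each feedback onset, computes the mean clustered entropy (and its
#' spike-normalized version) in the `window_s` seconds before and after
#' the onset; onsets too close to the session edges are skipped. Rest
#' sessions can be probed at matched virtual timepoints by passing the
#' same onset times.
#'
#' @param events spike events (`channel`, `time_s`).
#' @param feedback_times_s feedback onset times, seconds.
#' @param scheme a [cluster_scheme()].
#' @param t_start,t_end session span, seconds.
#' @param window_s comparison window (4 s, the unpredictable-stimulus
#'   duration).
#' @return data.frame with one row per usable onset: `time`, `pre`,
#'   `post`, `pre_norm`, `post_norm`; zero rows if no onset is usable.
#' @export
pre_post_feedback_entropy <- function(events, feedback_times_s, scheme,
                                      t_start, t_end, window_s = 4) {
  rows <- lapply(feedback_times_s, function(t0) {
    if (t0 - window_s < t_start || t0 + window_s > t_end) return(NULL)
    pre <- clustered_entropy(events, scheme, t0 - window_s, t0)
    post <- clustered_entropy(events, scheme, t0, t0 + window_s)
    data.frame(time = t0, pre = pre$mean, post = post$mean,
               pre_norm = normalized_entropy(pre$mean, sum(pre$window_spikes)),
               post_norm = normalized_entropy(post$mean, sum(post$window_spikes)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(time = numeric(0), pre = numeric(0), post = numeric(0),
                      pre_norm = numeric(0), post_norm = numeric(0))
  out
}

#' Centre of activity of an activity map
#'
#' The firing-count-weighted centroid of electrode positions relative to
#' a reference corner:
#' `CA = sum_k F_k [X_k - R_X, Y_k - R_Y] / sum_k F_k`,
#' with the reference at the bottom-left corner of the array.
#'
#' @param counts per-electrode spike counts `F_k`.
#' @param coords two-column matrix of electrode positions (X, Y).
#' @param ref reference point `(R_X, R_Y)`.
#' @return numeric length-2 vector `(CA_X, CA_Y)`.
#' @export
center_of_activity <- function(counts, coords, ref = c(0, 0)) {
  if (length(counts) != nrow(coords))
    stop("counts and coordinates must have equal length")
  tot <- sum(counts)
  if (tot <= 0) stop("centre of activity undefined: all counts are zero")
  c(sum(counts * (coords[, 1] - ref[1])),
    sum(counts * (coords[, 2] - ref[2]))) / tot
}

ca_per_bin <- function(events, coords, t_start, t_end, bin_s = 1) {
  n_bin <- floor((t_end - t_start) / bin_s + 1e-9)
  keep <- events$time_s >= t_start & events$time_s < t_start + n_bin * bin_s
  ev <- events[keep, , drop = FALSE]
  bin <- floor((ev$time_s - t_start) / bin_s)
  out <- matrix(NA_real_, n_bin, 2)
  if (nrow(ev)) {
    sx <- tapply(coords[ev$channel + 1L, 1], bin, sum)
    sy <- tapply(coords[ev$channel + 1L, 2], bin, sum)
    n <- tapply(rep(1, nrow(ev)), bin, sum)
    ii <- as.integer(names(n)) + 1L
    out[ii, 1] <- sx / n
    out[ii, 2] <- sy / n
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Centre-of-activity plasticity score
#'
#' CAs are computed in 1 s bins. The reference centroid is the mean CA
#' over the whole rest recording; the gameplay score is the mean
#' Euclidean distance from the mean CA of each consecutive 5 min
#' gameplay window to that centroid, and the rest score is the same
#' statistic for the rest recording's own 5 min windows against its own
#' centroid. A gameplay score exceeding the rest score indicates
#' activity reorganization beyond baseline drift.
#'
#' @param gameplay_events,rest_events spike events (`channel`, `time_s`).
#' @param coords electrode coordinate matrix (rows = channels).
#' @param gameplay_span,rest_span numeric length-2 `(start, end)` in
#'   seconds; rest must cover >= 10 min and gameplay >= 10 min.
#' @param bin_s CA sampling bin (1 s).
#' @param window_s aggregation window (300 s).
#' @return list with `gameplay`, `rest` (mean distances),
#'   `gameplay_distances`, `rest_distances`, `rest_centroid`.
#' @export
plasticity_score <- function(gameplay_events, rest_events, coords,
                             gameplay_span, rest_span,
                             bin_s = 1, window_s = 300) {
  if (diff(rest_span) < 2 * window_s - 1e-9)
    stop("rest reference must cover at least two aggregation windows")
  if (diff(gameplay_span) < 2 * window_s - 1e-9)
    stop("gameplay session must cover at least two aggregation windows")
  rest_ca <- ca_per_bin(rest_events, coords, rest_span[1], rest_span[2], bin_s)
  if (nrow(rest_ca) == 0) stop("no activity in the rest reference")
  centroid <- colMeans(rest_ca)

  window_dists <- function(events, span, ref) {
    n_w <- floor(diff(span) / window_s + 1e-9)
    vapply(seq_len(n_w) - 1L, function(w) {
      ca <- ca_per_bin(events, coords,
                       span[1] + w * window_s,
                       span[1] + (w + 1) * window_s, bin_s)
      if (nrow(ca) == 0) return(NA_real_)
      sqrt(sum((colMeans(ca) - ref)^2))
    }, numeric(1))
  }
  gd <- window_dists(gameplay_events, gameplay_span, centroid)
  rd <- window_dists(rest_events, rest_span, centroid)
  list(gameplay = mean(gd, na.rm = TRUE), rest = mean(rd, na.rm = TRUE),
       gameplay_distances = gd, rest_distances = rd,
       rest_centroid = centroid)
}

#' Low-order spatial DCT modes of an activity image
#'
#' Computes the 2-D type-II DCT coefficients (u, v) for u, v in 0..2 of
#' the per-electrode activity image and reports their absolute values
#' normalized to the image's mean activity, making the reported modes
#' invariant to overall activity scale. The four first-order asymmetry
#' modes (0,1), (0,2), (1,0), (2,0) - activity tilts and bowings along
#' each axis - are flagged. Index convention: u is the vertical (row)
#' frequency, v the horizontal (column) frequency.
#'
#' @param image numeric matrix of per-electrode activity (rows = grid
#'   rows, bottom row first).
#' @param max_order highest frequency index reported (2).
#' @return data.frame with `u`, `v`, `coef`, `abs_norm`, `asymmetry`.
#' @export
dct_modes <- function(image, max_order = 2L) {
  mu <- mean(image)
  if (!is.finite(mu) || mu == 0) stop("zero or undefined mean activity")
  nr <- nrow(image); nc <- ncol(image)
  Cr <- dct_basis(nr, max_order)
  Cc <- dct_basis(nc, max_order)
  coef <- Cr %*% image %*% t(Cc)
  grid <- expand.grid(u = 0:max_order, v = 0:max_order)
  grid$coef <- coef[cbind(grid$u + 1L, grid$v + 1L)]
  grid$abs_norm <- abs(grid$coef) / mu
  grid$asymmetry <- (grid$u + grid$v > 0) & (grid$u == 0 | grid$v == 0)
  grid
}

dct_basis <- function(n, max_order) {
  u <- 0:max_order
  b <- sqrt(2 / n) * cos(outer(u, 2 * (0:(n - 1)) + 1) * pi / (2 * n))
  b[1, ] <- sqrt(1 / n)
  b
}

#' Lagged cross-correlation between binned activity series
#'
#' Correlates `a(t)` with `b(t + lag)` over equal-length binned count
#' series (100 ms bins, one-bin lag by default, matching the
#' sensory-to-motor functional-connectivity analysis). A rank-based
#' variant is available for relationships with substantial nonlinearity,
#' as used for motor-motor synchrony.
#'
#' @param a,b equal-length numeric series.
#' @param lag lag in bins applied to `b`.
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation; `NA` with a warning for constant series.
#' @export
lagged_cross_correlation <- function(a, b, lag = 1L,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("series must have equal length")
  n <- length(a)
  if (lag >= n) stop("lag longer than the series")
  x <- a[seq_len(n - lag)]
  y <- b[seq_len(n - lag) + lag]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Fraction of exclusive motor-region events
#'
#' Events above noise (signed amplitude below -5 microvolts) are grouped
#' into 1 s bins per motor region; a bin is exclusive when exactly one
#' of the two regions contains at least one qualifying event. Returns
#' the fraction of exclusive bins over the analyzed span together with
#' the per-bin counts.
#'
#' @param events spike events (`channel`, `time_s`, `amplitude` in
#'   microvolts).
#' @param layout an [electrode_layout()].
#' @param t_start,t_end analyzed span, seconds.
#' @param bin_s bin length (1 s).
#' @param amplitude_max_uV qualifying threshold (-5).
#' @return list with `fraction`, `n_bins`, and `bins` (data.frame with
#'   per-bin motor1/motor2 qualifying counts).
#' @export
exclusive_motor_events <- function(events, layout, t_start, t_end,
                                   bin_s = 1, amplitude_max_uV = -5) {
  n_bin <- floor((t_end - t_start) / bin_s + 1e-9)
  reg <- layout$channels$region[events$channel + 1L]
  keep <- events$time_s >= t_start &
    events$time_s < t_start + n_bin * bin_s &
    events$amplitude < amplitude_max_uV &
    reg %in% c("motor1", "motor2")
  bin <- floor((events$time_s[keep] - t_start) / bin_s)
  tab <- table(factor(bin, levels = 0:(n_bin - 1L)),
               factor(reg[keep], levels = c("motor1", "motor2")))
  m1 <- as.numeric(tab[, 1]); m2 <- as.numeric(tab[, 2])
  exclusive <- xor(m1 > 0, m2 > 0)
  list(fraction = sum(exclusive) / n_bin, n_bins = n_bin,
       bins = data.frame(bin = 0:(n_bin - 1L), motor1 = m1, motor2 = m2,
                         exclusive = exclusive))
}

#' Normalized deviation from motor symmetry
#'
#' Z-scores a session's absolute motor-activity imbalance against the
#' population distribution of imbalances: sessions more than about one
#' deviation above the population mean imbalance tend not to perform.
#'
#' @param a1,a2 session activity in motor regions 1 and 2.
#' @param pop_mean,pop_sd population mean and SD of `|a1 - a2|` across a
#'   batch of sessions.
#' @return the deviation score.
#' @export
symmetry_deviation <- function(a1, a2, pop_mean, pop_sd) {
  if (pop_sd <= 0) stop("population SD must be positive")
  (abs(a1 - a2) - pop_mean) / pop_sd
}

#' Split rally records into the two analysis timepoints
#'
#' Rallies are assigned by their end time to T1 (minutes 0-5) or T2
#' (minutes 6-20); the transition minute 5-6 belongs to neither.
#' Sessions shorter than 20 minutes scale the boundaries proportionally,
#' with a warning.
#'
#' @param records rally records with an `end_tick` column.
#' @param ticks_per_second game tick rate.
#' @param session_min session duration, minutes.
#' @return list with `t1` and `t2` (subsets of `records`).
#' @export
split_timepoints <- function(records, ticks_per_second = 100,
                             session_min = 20) {
  if (NROW(records) == 0) stop("no rally records")
  scale <- session_min / 20
  if (session_min < 20)
    warning("session shorter than 20 min: timepoint boundaries scaled ",
            "proportionally")
  end_min <- records$end_tick / ticks_per_second / 60
  list(t1 = records[end_min < 5 * scale, , drop = FALSE],
       t2 = records[end_min >= 6 * scale & end_min <= 20 * scale, ,
                    drop = FALSE])
}

#' Hit-miss ratio at the two analysis timepoints
#'
#' Computes the hit-miss ratio (paddle hits per miss - the event-level
#' equivalent of average rally length) inside the T1 (minutes 0-5) and
#' T2 (minutes 6-20) windows of a session, and their difference, the
#' within-session learning contrast. Working from hit/miss events rather
#' than rally records makes the contrast well defined for the
#' no-feedback condition too, where the whole session is one rally but
#' contacts are still tallied.
#'
#' @param session a `pong_session` (see [run_session()]).
#' @return list with `t1`, `t2` (ratios) and `diff` (`t2 - t1`).
#' @export
timepoint_performance <- function(session) {
  ev <- session$events
  tps <- session$config$game$ticks_per_second
  scale <- session$config$duration_min / 20
  minute <- ev$tick / tps / 60
  ratio <- function(lo, hi) {
    k <- ev$kind[minute >= lo & minute < hi]
    sum(k == "paddle_hit") / max(sum(k == "miss"), 1)
  }
  t1 <- ratio(0, 5 * scale)
  t2 <- ratio(6 * scale, 20 * scale)
  list(t1 = t1, t2 = t2, diff = t2 - t1)
}

#' Exclude outliers by absolute Z score
#'
#' @param x numeric vector.
#' @param z_max exclusion threshold (3.29).
#' @return `x` with outliers removed.
#' @export
filter_outliers <- function(x, z_max = 3.29) {
  z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  x[!is.na(z) & abs(z) <= z_max]
}
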