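test_that("binary entropy follows the exact formula with the 0 log 0 convention", {
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0.25),
               -0.25 * log2(0.25) - 0.75 * log2(0.75))
  p <- seq(0, 1, by = 0.01)
  expect_equal(binary_entropy(p), binary_entropy(1 - p))  # symmetry
  expect_true(all(binary_entropy(p) <= 1))
  expect_equal(which.max(binary_entropy(p)), 51L)          # max at 0.5
  expect_error(binary_entropy(1.2), "\\[0, 1\\]")
})

test_that("the cluster scheme is 18 disjoint rectangles of 50 electrodes", {
  sc <- cluster_scheme()
  expect_length(sc, 18)
  expect_true(all(lengths(sc) == 50))
  all_ch <- unlist(sc)
  expect_false(anyDuplicated(all_ch) > 0)
  expect_true(all(all_ch %in% 0:1023))
  # rectangles: each cluster spans 10 consecutive rows x 5 columns
  for (cl in sc) {
    rows <- cl %% 32; cols <- cl %/% 32
    expect_equal(length(unique(rows)), 10)
    expect_equal(length(unique(cols)), 5)
    expect_equal(diff(range(rows)), 9)
    expect_equal(diff(range(cols)), 4)
  }
})

test_that("clustered entropy matches hand-computed rasters", {
  sc <- cluster_scheme()
  # no spikes anywhere: zero entropy
  ev <- raster_events(integer(0), numeric(0))
  out <- clustered_entropy(ev, sc, 0, 1)
  expect_equal(out$mean, 0)

  # every electrode fires in every window: p = 1, zero entropy
  ch <- unlist(sc)
  ev <- raster_events(rep(ch, 3), rep(c(0.05, 0.15, 0.25), each = length(ch)))
  out <- clustered_entropy(ev, sc, 0, 0.3)
  expect_equal(out$mean, 0)
  expect_true(all(out$p == 1))

  # exactly 25 of 50 electrodes per cluster per window: entropy exactly 1
  half <- unlist(lapply(sc, `[`, 1:25))
  ev <- raster_events(half, rep(0.05, length(half)))
  out <- clustered_entropy(ev, sc, 0, 0.1)
  expect_equal(out$mean, 1)

  # a known mixed case: one cluster with 10/50 electrodes in one window
  ev <- raster_events(sc[[4]][1:10], rep(0.05, 10))
  out <- clustered_entropy(ev, sc, 0, 0.1)
  expect_equal(out$series[1, 4], binary_entropy(0.2))
  expect_equal(out$mean, binary_entropy(0.2) / 18)

  # multiple spikes on one electrode count once for occupancy
  ev <- raster_events(rep(sc[[1]][1], 5), rep(0.01, 5) + 0:4 * 0.001)
  out <- clustered_entropy(ev, sc, 0, 0.1)
  expect_equal(out$p[1, 1], 1 / 50)
  expect_equal(out$window_spikes[1], 5)
})

test_that("entropy is invariant to relabelling electrodes within a cluster", {
  sc <- cluster_scheme()
  rng <- rng_stream(3)
  ch <- rng_eval(rng, sample(sc[[7]], 20))
  t <- rng_eval(rng, runif(20, 0, 0.1))
  base <- clustered_entropy(raster_events(ch, t), sc, 0, 0.1)$mean
  perm <- clustered_entropy(raster_events(sample(sc[[7]], 20), t),
                            sc, 0, 0.1)$mean
  expect_equal(base, perm)
})

test_that("normalization divides entropy by spike counts with a zero convention", {
  expect_equal(normalized_entropy(0, 100), 0)
  expect_equal(normalized_entropy(0.8, 400), 0.002)
  expect_equal(normalized_entropy(c(0.5, 0.5), c(100, 200)),
               c(0.005, 0.0025))
  expect_equal(normalized_entropy(0.7, 0), 0)
  expect_error(normalized_entropy(c(1, 2), 1), "aligned")
})

test_that("pre/post feedback entropy compares matched 4 s windows", {
  sc <- cluster_scheme()
  # raster where occupancy jumps from 5/50 to 25/50 at t = 10 s:
  # entropy is monotone on [0, 0.5], so post > pre
  pre_ch <- unlist(lapply(sc, `[`, 1:5))
  post_ch <- unlist(lapply(sc, `[`, 1:25))
  wins <- seq(0, 9.9, by = 0.1)
  ev <- rbind(
    raster_events(rep(pre_ch, length(wins)),
                  rep(wins + 0.05, each = length(pre_ch))),
    raster_events(rep(post_ch, length(wins)),
                  rep(10 + wins + 0.05, each = length(post_ch))))
  out <- pre_post_feedback_entropy(ev, 10, sc, 0, 20)
  expect_equal(nrow(out), 1)
  expect_gt(out$post, out$pre)
  expect_equal(out$pre, binary_entropy(0.1), tolerance = 1e-12)
  expect_equal(out$post, binary_entropy(0.5), tolerance = 1e-12)

  # onsets too near the session edges are skipped; none is not an error
  out <- pre_post_feedback_entropy(ev, c(1, 19.5), sc, 0, 20)
  expect_equal(nrow(out), 0)

  # a stationary raster shows no pre/post difference
  out <- pre_post_feedback_entropy(
    raster_events(rep(pre_ch, 100), rep(seq(0.05, 9.95, by = 0.1),
                                        each = length(pre_ch))),
    5, sc, 0, 10)
  expect_equal(out$pre, out$post)
})

test_that("the centre of activity is the count-weighted centroid", {
  # single active electrode
  coords <- cbind(c(1, 6), c(1, 1))
  expect_equal(center_of_activity(c(3, 0), coords), c(1, 1))
  # hand evaluation: counts 4 at (1,1) and 1 at (6,1), reference (0,0)
  expect_equal(center_of_activity(c(4, 1), coords), c(2, 1))
  # uniform counts on a symmetric grid: centroid of the grid
  g <- as.matrix(expand.grid(0:3, 0:3))
  expect_equal(center_of_activity(rep(2, 16), g), c(1.5, 1.5))
  # reference translation shifts the CA by exactly minus the translation
  ca0 <- center_of_activity(c(4, 1), coords)
  ca1 <- center_of_activity(c(4, 1), coords, ref = c(2, -3))
  expect_equal(ca1, ca0 - c(2, -3))
  # permutation invariance
  perm <- c(2, 1)
  expect_equal(center_of_activity(c(4, 1)[perm], coords[perm, ]), ca0)
  expect_error(center_of_activity(c(0, 0), coords), "zero")
})

test_that("plasticity scores separate shifted gameplay from stationary rest", {
  rng <- rng_stream(9)
  coords <- as.matrix(expand.grid(0:31, 0:31))
  n_ch <- 1024
  mk_events <- function(rate_per_ch, t0, t1, channels = 0:(n_ch - 1)) {
    n <- rng_eval(rng, rpois(1, rate_per_ch * length(channels) * (t1 - t0)))
    raster_events(rng_eval(rng, sample(channels, n, replace = TRUE)),
                  rng_eval(rng, runif(n, t0, t1)))
  }
  rest <- mk_events(0.3, 0, 600)
  # identical process: scores match within resampling error
  game_null <- mk_events(0.3, 0, 600)
  ps <- plasticity_score(game_null, rest, coords, c(0, 600), c(0, 600))
  expect_lt(abs(ps$gameplay - ps$rest), 0.35)

  # gameplay with counts shifted toward one side of the array
  left <- which(coords[, 1] < 8) - 1L
  game_shift <- rbind(mk_events(0.3, 0, 600), mk_events(0.6, 0, 600, left))
  ps2 <- plasticity_score(game_shift, rest, coords, c(0, 600), c(0, 600))
  expect_gt(ps2$gameplay, ps2$rest)

  # all CAs identical: both scores zero
  one <- raster_events(rep(5L, 1199), seq(0.5, 599.5, by = 0.5))
  ps3 <- plasticity_score(one, one, coords, c(0, 600), c(0, 600))
  expect_equal(ps3$gameplay, 0)
  expect_equal(ps3$rest, 0)
  expect_error(plasticity_score(one, one, coords, c(0, 300), c(0, 600)),
               "at least two")
})

test_that("DCT modes match brute-force basis summation and flag asymmetries", {
  img <- matrix(as.numeric(outer(1:8, 1:8, function(i, j)
    (i %% 2) * 3 + j)), 8, 8)
  dm <- dct_modes(img)
  for (k in seq_len(nrow(dm))) {
    expect_equal(dm$coef[k], dct2_brute(img, dm$u[k], dm$v[k]),
                 tolerance = 1e-10)
  }
  expect_equal(dm$asymmetry, (dm$u + dm$v > 0) & (dm$u == 0 | dm$v == 0))

  # flat image: all non-DC coefficients vanish
  dm <- dct_modes(matrix(4, 10, 10))
  expect_true(all(abs(dm$coef[dm$u + dm$v > 0]) < 1e-10))

  # image linear along columns: only (0, v) modes non-zero
  lin <- matrix(rep(1:10, each = 6), 6, 10)
  dm <- dct_modes(lin)
  expect_gt(abs(dm$coef[dm$u == 0 & dm$v == 1]), 0.1)
  expect_lt(abs(dm$coef[dm$u == 1 & dm$v == 0]), 1e-10)

  # reported modes are scale-invariant (normalized to mean activity)
  d1 <- dct_modes(img)$abs_norm
  d2 <- dct_modes(img * 37.5)$abs_norm
  expect_equal(d1, d2)
  expect_error(dct_modes(matrix(0, 4, 4)), "zero")
})

test_that("lagged cross-correlation is exact on shifted series", {
  set.seed(2)
  a <- rpois(400, 5)
  b <- c(0, a[-400])            # b(t) = a(t - 1): at lag 1, correlation 1
  expect_equal(lagged_cross_correlation(a, b, lag = 1), 1)
  expect_equal(lagged_cross_correlation(a, -b, lag = 1), -1)
  # independent series: correlation near zero
  r <- lagged_cross_correlation(rpois(2000, 5), rpois(2000, 5))
  expect_lt(abs(r), 3 / sqrt(2000))
  # rank-based variant
  expect_equal(lagged_cross_correlation(a, b, 1, method = "spearman"), 1)
  expect_warning(r0 <- lagged_cross_correlation(rep(1, 10), rpois(10, 2)),
                 "constant")
  expect_true(is.na(r0))
  expect_error(lagged_cross_correlation(1:5, 1:6), "equal length")
})

test_that("exclusive motor events follow the 1 s / -5 uV rule", {
  lay <- electrode_layout(3)
  m1 <- lay$region_channels$motor1[1]
  m2 <- lay$region_channels$motor2[1]
  # alternating bins firing only motor1 then only motor2: fraction 1
  ev <- raster_events(rep(c(m1, m2), 5), (0:9) + 0.5)
  out <- exclusive_motor_events(ev, lay, 0, 10)
  expect_equal(out$fraction, 1)
  # both regions firing in every bin: fraction 0
  ev <- raster_events(rep(c(m1, m2), each = 10),
                      rep((0:9) + 0.5, 2))
  expect_equal(exclusive_motor_events(ev, lay, 0, 10)$fraction, 0)
  # constructed raster: 30 exclusive bins out of 100
  ev <- rbind(raster_events(rep(m1, 30), (0:29) + 0.5),
              raster_events(rep(c(m1, m2), each = 20),
                            rep((30:49) + 0.5, 2)))
  expect_equal(exclusive_motor_events(ev, lay, 0, 100)$fraction, 0.3)
  # events above the amplitude threshold do not qualify
  ev <- raster_events(rep(m1, 10), (0:9) + 0.5, amplitude = -3)
  expect_equal(exclusive_motor_events(ev, lay, 0, 10)$fraction, 0)
})

test_that("symmetry deviation is a z-score of the absolute imbalance", {
  expect_equal(symmetry_deviation(5, 5, 2, 1), -2)   # |a1-a2| = 0
  expect_equal(symmetry_deviation(7, 3, 4, 2), 0)    # at the mean
  expect_equal(symmetry_deviation(9, 3, 4, 2), 1)    # one SD above
  expect_error(symmetry_deviation(1, 2, 0, 0), "positive")
})

test_that("rallies split into T1 and T2 with the transition minute excluded", {
  recs <- data.frame(end_tick = c(3, 5.5, 12, 4.99, 6, 20) * 60 * 100,
                     hits = 1:6)
  tp <- split_timepoints(recs)
  expect_equal(tp$t1$hits, c(1, 4))       # ends at minutes 3 and 4.99
  expect_equal(tp$t2$hits, c(3, 5, 6))    # minutes 12, 6, 20
  expect_false(2 %in% c(tp$t1$hits, tp$t2$hits))  # minute 5.5 excluded
  expect_warning(split_timepoints(recs, session_min = 10), "scaled")
  expect_error(split_timepoints(recs[0, ]), "no rally")
})

test_that("outlier filtering removes |Z| > 3.29", {
  x <- c(rep(1, 20), rep(-1, 20), 50)
  expect_false(50 %in% filter_outliers(x))
  expect_equal(sort(unique(filter_outliers(x))), c(-1, 1))
  expect_equal(filter_outliers(c(1, 2, 3)), c(1, 2, 3))
})
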