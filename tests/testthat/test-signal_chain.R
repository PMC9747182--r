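# Reference coefficients computed once with an independent filter-design
# implementation (SciPy's Bessel designer, -3 dB magnitude normalization,
# bilinear transform) and frozen here.
HP_B_REF <- c(0.978911226146474, -1.95782245229295, 0.978911226146474)
HP_A_REF <- c(1.0, -1.95752384744031, 0.958121057145591)
LP_B_REF <- c(0.000157054963835185, 0.000157054963835185)
LP_A_REF <- c(1.0, -0.99968589007233)

test_that("Bessel designs match the independent reference coefficients", {
  hp <- bessel_highpass2(100, 20000)
  expect_equal(hp$b, HP_B_REF, tolerance = 1e-9)
  expect_equal(hp$a, HP_A_REF, tolerance = 1e-9)
  lp <- bessel_lowpass1(1, 20000)
  expect_equal(lp$b, LP_B_REF, tolerance = 1e-9)
  expect_equal(lp$a, LP_A_REF, tolerance = 1e-9)
  # cutoff is the -3 dB point; low-pass has unity DC gain
  expect_equal(filter_gain(hp, 100), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(filter_gain(lp, 0), 1, tolerance = 1e-9)
})

test_that("the high-pass kills DC and passes 1 kHz at its analytic gain", {
  hp <- bessel_highpass2()
  x <- matrix(rep(5, 20000), ncol = 1)
  y <- iir_step(iir_init(hp, 1), x)$y
  expect_lt(max(abs(tail(y, 1000))), 1e-6)

  t <- (0:19999) / 20000
  x <- matrix(sin(2 * pi * 1000 * t), ncol = 1)
  y <- iir_step(iir_init(hp, 1), x)$y
  settled <- 5001:20000                     # whole periods, post-transient
  amp <- sqrt(mean(y[settled]^2) / mean(x[settled]^2))
  expect_equal(amp, filter_gain(hp, 1000), tolerance = 1e-3)
})

test_that("filter output equals brute-force direct-form convolution/recursion", {
  hp <- bessel_highpass2()
  set.seed(42)
  x <- rnorm(400)
  y <- as.numeric(iir_step(iir_init(hp, 1), matrix(x, ncol = 1))$y)
  # oracle: direct evaluation of the difference equation
  yo <- numeric(400)
  for (n in seq_along(x)) {
    acc <- 0
    for (k in seq_along(hp$b))
      if (n - k + 1 >= 1) acc <- acc + hp$b[k] * x[n - k + 1]
    for (k in 2:length(hp$a))
      if (n - k + 1 >= 1) acc <- acc - hp$a[k] * yo[n - k + 1]
    yo[n] <- acc
  }
  expect_equal(y, yo, tolerance = 1e-10)
})

test_that("streaming chunked filtering is identical to batch filtering", {
  hp <- bessel_highpass2()
  set.seed(1)
  x <- matrix(rnorm(30000 * 3), ncol = 3)
  batch <- iir_step(iir_init(hp, 3), x)$y
  st <- iir_init(hp, 3)
  pieces <- list()
  splits <- c(1, 7, 1234, 15000, 29999, 30000)
  start <- 1
  for (s in splits) {
    out <- iir_step(st, x[start:s, , drop = FALSE])
    st <- out$state
    pieces[[length(pieces) + 1]] <- out$y
    start <- s + 1
  }
  expect_equal(do.call(rbind, pieces), batch, tolerance = 1e-12)
})

test_that("the envelope tracks the rectified signal with unity DC gain", {
  lp <- bessel_lowpass1()
  y <- iir_step(iir_init(lp, 1), matrix(rep(0, 1000), ncol = 1))$y
  expect_true(all(y == 0))
  # constant |x| = c held for several time constants converges to c
  y <- iir_step(iir_init(lp, 1), matrix(rep(3, 60000), ncol = 1))$y
  expect_equal(tail(as.numeric(y), 1), 3, tolerance = 0.05)
  # white noise: envelope converges to the mean absolute value
  set.seed(9)
  x <- abs(matrix(rnorm(120000, 0, 2), ncol = 1))
  y <- iir_step(iir_init(lp, 1), x)$y
  expect_equal(mean(tail(as.numeric(y), 20000)), 2 * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("the detector recovers injected spikes and is quiet on pure noise", {
  fs <- 20000
  n_ch <- 8
  dur <- 6
  n <- fs * dur
  rng <- rng_stream(77)
  # ground-truth spikes, >2 s (warm-up) into the trace, 1 ms apart min
  truth <- do.call(rbind, lapply(seq_len(n_ch) - 1L, function(ch) {
    t <- sort(rng_eval(rng, sample(seq(2.2 * fs, n - 100), 15)))
    t <- t[c(TRUE, diff(t) > 40)]
    data.frame(channel = ch, sample = as.integer(t))
  }))
  v <- synth_voltage(truth[order(truth$sample), ], n, n_ch, noise_sd = 3,
                     snr = 8, rng = rng_stream(78))
  ev <- spike_detect_chain(v, fs = fs, k = 6)
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    d <- ev$sample[ev$channel == truth$channel[i]] - truth$sample[i]
    if (any(abs(d) <= 20)) hits <- hits + 1
  }
  expect_gte(hits / nrow(truth), 0.95)
  false_pos <- nrow(ev) - hits
  expect_lt(false_pos / (dur - 2) / n_ch, 1)   # < 1 per second per channel

  # determinism: same input, same event stream
  expect_identical(ev, spike_detect_chain(v, fs = fs, k = 6))
})

test_that("the detector is self-calibrating: input scale leaves times unchanged", {
  fs <- 20000
  truth <- data.frame(channel = 0L,
                      sample = as.integer(seq(2.5 * fs, 5.5 * fs, by = 4000)))
  v <- synth_voltage(truth, 6 * fs, 1, noise_sd = 3, snr = 8,
                     rng = rng_stream(5))
  e1 <- spike_detect_chain(v, fs)
  e2 <- spike_detect_chain(v * 7.3, fs)
  expect_equal(e1$sample, e2$sample)
  expect_equal(e2$amplitude, 7.3 * e1$amplitude, tolerance = 1e-9)
})

test_that("no events are emitted below threshold or during warm-up", {
  v <- matrix(rnorm(20000 * 2, 0, 3), ncol = 2)   # 1 s of pure noise
  set.seed(3)
  ev <- spike_detect_chain(v, warmup_s = 2)       # all inside warm-up
  expect_equal(nrow(ev), 0)
  hp <- matrix(0.1, 2000, 1)
  env <- matrix(1, 2000, 1)
  expect_equal(nrow(detect_spikes(hp, env, k = 6, warmup_samples = 0L)), 0)
})

test_that("command blinding drops exactly the events inside logged windows", {
  ev <- data.frame(channel = 0L,
                   sample = c(50L, 100L, 150L, 199L, 200L, 500L),
                   amplitude = -20)
  out <- apply_blinding(ev, stim_samples = 100L, window_samples = 100L)
  expect_equal(out$sample, c(50L, 200L, 500L))  # [100, 200) dropped

  # artifacts at a logged command are fully removed on all channels
  truth <- data.frame(channel = 0:63, sample = rep(60000L, 64))
  v <- synth_voltage(truth, 80000, 64, noise_sd = 3, snr = 8,
                     stim_samples = 60000L, rng = rng_stream(2))
  det <- spike_detect_chain(v)
  blinded <- apply_blinding(det, stim_samples = 60000L,
                            window_samples = 100L)
  in_window <- blinded$sample >= 60000 & blinded$sample < 60100
  expect_equal(sum(in_window), 0)

  # blinding is monotone in window length and touches nothing outside
  w1 <- apply_blinding(ev, 100L, 50L)
  w2 <- apply_blinding(ev, 100L, 150L)
  expect_gte(nrow(w1), nrow(w2))
  expect_true(all(out$sample %in% ev$sample))
  expect_error(apply_blinding(ev, c(200L, 100L)), "sorted")
})

test_that("consensus blinding uses the >15 large-spike rule", {
  mk <- function(n_big) {
    data.frame(channel = seq_len(n_big + 2) - 1L,
               sample = rep(1000L, n_big + 2),
               amplitude = c(rep(-80000, n_big), -50, -50))
  }
  out16 <- apply_blinding(mk(16), integer(0), mode = "consensus")
  expect_equal(nrow(out16), 0)        # 16 large spikes: frame blinded
  out15 <- apply_blinding(mk(15), integer(0), mode = "consensus")
  expect_equal(nrow(out15), 17)       # 15 large spikes: frame retained
})
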