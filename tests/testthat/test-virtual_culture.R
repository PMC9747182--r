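make_culture <- function(profile = "learner_human", seed = 3, ...) {
  culture_init(culture_profile(profile, ...), electrode_layout(3),
               rng_stream(seed), duration_s = 60)
}

test_that("profiles enforce the control-condition constraints", {
  for (nm in c("media_only", "inactive_cells", "in_silico_random")) {
    p <- culture_profile(nm)
    expect_equal(p$evoked_gain, 0)
    expect_equal(p$eta_potentiate, 0)
    expect_equal(p$eta_perturb, 0)
  }
  expect_true(culture_profile("in_silico_random")$bypass)
  expect_error(culture_profile("media_only", evoked_gain = 5), "control")
  expect_error(culture_profile("learner_human", baseline_median_hz = -1),
               ">= 0")
})

test_that("profile presets ship as JSON and round-trip the constructor", {
  for (nm in c("learner_human", "learner_mouse", "media_only",
               "inactive_cells", "in_silico_random")) {
    path <- system.file("extdata", "profiles", paste0(nm, ".json"),
                        package = "neuropong")
    expect_true(nzchar(path))
    p <- read_culture_profile(path)
    expect_equal(unclass(p), unclass(culture_profile(nm)))
  }
  tmp <- tempfile(fileext = ".json")
  write_culture_profile(culture_profile("learner_mouse", asymmetry = 0.5),
                        tmp)
  expect_equal(read_culture_profile(tmp)$asymmetry, 0.5)
})

test_that("the initial coupling has no preferred motor direction", {
  cult <- make_culture()
  expect_equal(cult$Wreg[, 1], cult$Wreg[, 2], tolerance = 1e-12)
  expect_equal(rowSums(cult$W), rep(1, 8), tolerance = 1e-12)
})

test_that("culture stepping is deterministic under a fixed seed", {
  pulses <- list(site = c(2L, 5L), amplitude_mV = c(75, 150))
  run <- function() {
    cult <- make_culture(seed = 11)
    lapply(0:20, function(tk) culture_step(cult, pulses, tk, "channel"))
  }
  expect_identical(run(), run())
})

test_that("media-only cultures show baseline rates regardless of stimulation", {
  n <- 400
  count_rate <- function(pulses) {
    cult <- make_culture("media_only", seed = 5)
    tot <- 0
    for (tk in 0:(n - 1)) tot <- tot +
        sum(culture_step(cult, pulses, tk)$counts)
    tot / (n * 0.01)
  }
  r_stim <- count_rate(list(site = 0:7, amplitude_mV = rep(150, 8)))
  cult <- make_culture("media_only", seed = 5)
  base <- sum(cult$rates)
  # aggregate event rate stays at baseline: no evoked response at all
  expect_equal(r_stim, base, tolerance = 0.15)
})

test_that("mean evoked spikes per pulse equal the evoked gain", {
  # single 75 mV pulse, kernel mass 1: expected added spikes = evoked_gain
  gain <- 30
  cult <- make_culture(seed = 21, evoked_gain = gain,
                       baseline_median_hz = 1e-6, burst_rate_hz = 0)
  total <- 0
  n_trials <- 400
  for (i in seq_len(n_trials)) {
    tk0 <- (i - 1) * 10L
    total <- total + sum(culture_step(cult, list(site = 3L,
                                                 amplitude_mV = 75),
                                      tk0)$counts)
    for (d in 1:9) total <- total +
        sum(culture_step(cult, NULL, tk0 + d)$counts)
  }
  mean_evoked <- total / n_trials
  expect_equal(mean_evoked, gain, tolerance = 3 * sqrt(gain / n_trials) / gain)
  # amplitude scaling: a 150 mV pulse evokes twice the response
  cult2 <- make_culture(seed = 22, evoked_gain = gain,
                        baseline_median_hz = 1e-6, burst_rate_hz = 0)
  total2 <- 0
  for (i in seq_len(n_trials)) {
    tk0 <- (i - 1) * 10L
    total2 <- total2 + sum(culture_step(cult2, list(site = 3L,
                                                    amplitude_mV = 150),
                                        tk0)$counts)
    for (d in 1:9) total2 <- total2 +
        sum(culture_step(cult2, NULL, tk0 + d)$counts)
  }
  expect_equal(total2 / total, 2, tolerance = 0.15)
})

test_that("feedback updates follow their labels", {
  cult <- make_culture(seed = 31)
  W0 <- cult$W
  apply_feedback(cult, "none")
  expect_identical(cult$W, W0)

  # predictable with zero eligibility: no change
  apply_feedback(cult, "predictable")
  expect_identical(cult$W, W0)

  # unpredictable: zero-mean multiplicative noise, bounded weights
  apply_feedback(cult, "unpredictable")
  expect_false(identical(cult$W, W0))
  expect_true(all(cult$W >= 0 & cult$W <= cult$profile$w_max))
  expect_equal(mean(cult$W - W0), 0, tolerance = 1e-3)

  # silent gap: same kind of effect, smaller magnitude
  c1 <- make_culture(seed = 32)
  c2 <- make_culture(seed = 32)
  apply_feedback(c1, "unpredictable")
  apply_feedback(c2, "silent_gap")
  expect_gt(sd(c1$W - make_culture(seed = 32)$W),
            sd(c2$W - make_culture(seed = 32)$W))
  expect_error(apply_feedback(cult, "bogus"), "unknown")
})

test_that("credited potentiation monotonically grows the correct drive difference", {
  cult <- make_culture(seed = 41)
  site <- 6L
  diffs <- numeric(12)
  for (k in 1:12) {
    # stimulate the site, then credit motor 1 as the acting region
    for (rep in 1:5) {
      culture_step(cult, list(site = site, amplitude_mV = 75),
                   (k - 1) * 5L + rep - 1L)
      culture_credit(cult, 1L, (k - 1) * 5L + rep - 1L)
    }
    apply_feedback(cult, "predictable", (k - 1) * 5L + 4L)
    diffs[k] <- cult$Wreg[site + 1L, 1] - cult$Wreg[site + 1L, 2]
  }
  expect_true(all(diff(diffs) >= -1e-12))
  expect_gt(diffs[12], diffs[1])
})

test_that("baseline motor asymmetry degrades achievable rally length", {
  levels <- c(0, 0.5, 1, 2)
  means <- vapply(levels, function(a) {
    mean(vapply(1:4, function(sd) {
      s <- run_session(session_config("stimulus", seed = sd,
                                      duration_min = 10,
                                      profile_options = list(asymmetry = a)))
      s$summary$avg_rally_length
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(levels, means, method = "spearman"), 0)
})

test_that("a rest session leaves the coupling untouched", {
  cfg <- session_config("rest", seed = 17, duration_min = 1)
  s <- run_session(cfg)
  cult <- culture_init(culture_profile("learner_human"), electrode_layout(3),
                       rng_substream(17L, "culture"), 60)
  expect_equal(s$final_coupling, cult$Wreg, tolerance = 1e-12)
  expect_equal(nrow(s$stim_log), 0)
})

test_that("synthetic voltage renders spikes at their samples over noise", {
  ev <- data.frame(channel = c(0L, 1L), sample = c(100L, 300L))
  v <- synth_voltage(ev, 500, 2, noise_sd = 0, spike_uV = 24)
  expect_equal(which.min(v[, 1]) - 1L, 100L)   # negative peak at the event
  expect_equal(which.min(v[, 2]) - 1L, 300L)
  expect_equal(min(v[, 1]), -24)
  v0 <- synth_voltage(ev[0, ], 100, 2, noise_sd = 0)
  expect_true(all(v0 == 0))
  # overlapping events sum linearly
  ev2 <- data.frame(channel = c(0L, 0L), sample = c(100L, 100L))
  v2 <- synth_voltage(ev2, 500, 1, noise_sd = 0, spike_uV = 24)
  expect_equal(min(v2), 2 * min(v[, 1]), tolerance = 1e-12)
})

test_that("layout switching remaps regions but not culture properties", {
  cult <- make_culture(seed = 51)
  rates0 <- cult$rates; W0 <- cult$W
  culture_set_layout(cult, electrode_layout(0))
  expect_identical(cult$rates, rates0)
  expect_identical(cult$W, W0)
  expect_equal(sum(cult$region_n), 1024)
  # region sums now reflect the new assignment
  oracle <- matrix(0, 8, 3)
  for (r in 1:3) oracle[, r] <-
      rowSums(W0[, cult$region_index == r, drop = FALSE])
  expect_equal(cult$Wreg, oracle)
})
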