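---
title: "Closed-loop embodiment of a spiking culture: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop embodiment of a spiking culture: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropong)
```

## The system

`neuropong` simulates a closed-loop multielectrode-array (MEA) embodiment
experiment: a cultured neural network is "embodied" in a game of Pong by
wiring a simulated game world to the array in both directions. The loop,
advanced once per 10 ms spike-count bin (200 samples at 20 kHz), is:

1. **Sensory coding.** The ball's height selects one of 8 stimulation
   sites (place code, 8 equal bins bottom-to-top) and its distance from
   the opposing wall sets the pulse rate, linearly from 4 Hz at the far
   wall to 40 Hz at the paddle wall (rate code). Pulses are biphasic,
   75 mV.
2. **Culture.** Spikes are produced by the virtual culture (below) - or,
   in the full-voltage path, detected from synthesized traces by the
   Bessel IIR chain.
3. **Motor decoding.** Spikes are counted in two predefined motor
   regions; counts are divided by a gain correction factor (each
   region's smoothed rate over a 20 Hz target, clamped to [0.1, 10]) and
   the larger corrected drive moves the paddle one step up (region 1) or
   down (region 2); ties leave it still. Nothing else is learned or
   weighted on the decoding side.
4. **Outcome feedback.** Under the *stimulus* condition a miss triggers
   the unpredictable stimulus (4 s of 150 mV pulses at exponential
   inter-pulse intervals averaging 200 ms - memoryless, hence maximally
   unpredictable at the 5 Hz aggregate rate - at uniformly random sites,
   then 4 s of rest) and a hit triggers the predictable stimulus
   (all 8 sites synchronously at 100 Hz for 100 ms at 75 mV, briefly
   replacing sensory coding). The *silent* condition spans the same
   windows with no stimulation; *no-feedback* delivers nothing and the
   ball bounces off the back wall on a miss, so the session is a single
   uninterrupted rally; *rest* runs the game from spontaneous activity
   with no stimulation at all.

A rally is one serve-to-miss episode; performance is the hit-miss ratio
(average rally length), with aces (zero-hit rallies) and long rallies
(strictly more than 3 hits) as secondary metrics. The within-session
learning contrast compares minutes 0-5 (T1) against minutes 6-20 (T2).

## The game world

The field is normalized to 100 x 100 units so positions read as
percentages. Parameters with no canonical value in this class of system are exposed
as configuration with these defaults: ball speed of one wall-to-wall
traverse per 6 s (about 0.167 units/tick), paddle half-height 12.5 units
(a quarter of the field), paddle step 1 unit per commanded tick, and a
serve cone of +-60 degrees about the horizontal with random direction.
Speed is conserved exactly across specular bounces.

The paddle starts each session at a uniformly random admissible height.
This matters: a fixed centred start gives every condition an early
hit-rate advantage that decays as the paddle diffuses toward its
stationary (near-uniform) position distribution, which would contaminate
the T2 - T1 contrast with a spurious decline. A uniform start is the
stationary distribution, so the null expectation of the contrast is zero.

## The virtual culture

The culture is a deliberately minimal generative stand-in for an MEA
recording - enough structure to exercise every closed-loop mechanism,
and no more, so that closed-loop properties are attributable to the
embodiment machinery rather than to model sophistication. It emulates:

* **Baseline firing:** per-channel Poisson processes with a log-normal
  rate map (median 0.25 Hz per channel, sdlog 0.8). The median is chosen
  for detected (6-sigma-thresholded) spike rates and, equally
  importantly, puts motor-region aggregate rates near 60 Hz - inside the
  band where the 20 Hz-target gain correction actually operates. At a
  1 Hz median, region aggregates (~330 Hz) pin both correction factors
  at the upper clamp and the normalization does nothing.
* **Evoked responses:** each pulse on site *s* adds spikes with expected
  total `evoked_gain x (amplitude / 75 mV)` (default 30 per 75 mV
  pulse), distributed over channels in proportion to the coupling row
  `W[s, ]` and over time by a short latency kernel (0-30 ms, mean
  ~9 ms).
* **Synchronized bursts:** population events at 0.1 Hz, 300 ms long,
  adding 10 Hz to every channel, so the entropy and correlation
  statistics see realistic synchrony.
* **Signed amplitudes:** event amplitudes are drawn log-normal around
  -20 uV so the "below -5 uV" exclusive-event criterion is meaningful.

The initial coupling of each site is jittered around uniform, normalized
to unit total, and then *balanced* so the site's total coupling to motor
region 1 equals that to motor region 2. The motor regions necessarily
differ by a few channels (398 channels cannot split into four equal
geometric blocks), and without balancing that bookkeeping artifact gives
every site a fixed directional bias. An untrained culture should have no
preferred direction; directional structure must be produced by training,
or injected explicitly through the `asymmetry` parameter, which scales
motor-1 baseline rates by `1 + asymmetry` and motor-2 by its inverse.

### Plasticity

Learning operates on the site-by-channel coupling `W` through three
channels, gated by feedback:

* **Eligibility (stimulus-response-action coincidence).** After each
  decoded bin, the evoked spikes that landed in the bin are credited to
  their stimulation sites *for the region whose activity won the decode*
  (`culture_credit()`). This action gate is essential: raw evoked-spike
  eligibility is symmetric across the two motor regions and carries no
  directional information, so potentiating along it cannot teach a
  mapping. With the gate, eligibility records "when the ball was at
  height *s*, this region moved the paddle". Traces decay with a 2 s
  constant, matching the final-approach timescale of a rally.
* **Potentiation (predictable feedback).** A hit injects a fixed mass
  `eta_potentiate` (default 0.5) of coupling, distributed over
  (site, region) pairs by their share of the eligibility and within a
  region by the existing coupling profile. This is reward-modulated
  Hebbian learning: mappings active during a successful interception are
  reinforced.
* **Perturbation (unpredictable feedback).** A miss adds zero-mean
  multiplicative noise (`eta_perturb`, default 0.05) to every weight,
  destabilizing the mapping that failed. The silent gap applies the same
  kind of perturbation at `eta_silent = 0.02`.

Under the silent condition the explicit reinforcement burst is absent,
but a hit still has its predictable sensory consequence - the rally
continues and the patterned sensory stream resumes. The model treats
this as implicit reinforcement: hit potentiation scaled by
`silent_hit_scale = 0.3`. Without any reinforcement channel, silent
sessions can only diffuse away from the balanced-coupling optimum and
performance *declines*; with it, the silent condition learns, more
slowly than the stimulus condition, which is the qualitative ordering
the simulator is designed to reproduce as a tunable default. Weights are
clipped to `[0, 0.05]` elementwise; eligibility-free feedback changes
nothing, and rest sessions (no stimulation, no feedback) leave `W`
untouched.

### Control profiles

`media_only` (noise-floor events at 0.05 Hz/channel), `inactive_cells`
(0.01 Hz), and `in_silico_random` (healthy-rate iid motor counts with no
stimulus coupling) all have zero evoked gain and zero plasticity; the
profile constructor enforces this. They share the full closed-loop code
path, so "no improvement in controls" is a property of the system, not
of a separate branch.

### What the culture does *not* emulate

No membrane or synaptic dynamics, no conductances, no spatial
propagation, no development or homeostasis; evoked responses are
memoryless Poisson; plasticity is a two-rule caricature. Consequently,
passing tests demonstrate that the *embodiment machinery* (coding,
decoding, gain, feedback scheduling, logging, statistics) behaves as
specified and that the designed learning ordering emerges from the
closed loop - they say nothing quantitative about living cultures, and no
quantitative match to any living-culture experiment is attempted or
attainable.

## Spike detection

The detector mirrors a real-time IIR chain: a causal 2nd-order Bessel
high-pass at 100 Hz removes drift; the absolute value is smoothed by a
1st-order Bessel low-pass at 1 Hz into a noise envelope; an event fires
when `|filtered| > k x envelope` with `k = 6` ("six sigma"). Numerical
choices:

* Filters are designed from the analog Bessel prototype (poles of
  `s^2 + 3s + 3`, magnitude-normalized so the cutoff is the -3 dB
  point) and discretized by the bilinear transform with pre-warping at
  the cutoff - standard, reproducible coefficients, verified in the
  tests against an independently computed reference design.
* Streaming chunked filtering is exactly equal to batch filtering (the
  state carries enough input/output history for chunks of any length,
  including shorter than the filter order).
* A 1 ms per-channel refractory hold prevents double counting; the
  first 2 s of a stream emit no events while the 1 Hz envelope settles.
* Because the threshold is proportional to the tracked envelope, the
  detector is scale-free: rescaling the input voltage rescales
  amplitudes but leaves event times unchanged.
* Command-count blinding drops every event within a configurable window
  (default 100 samples = 5 ms) after any logged stimulation command, on
  all channels. The legacy consensus mode (blind frames with more than
  15 simultaneous events above 75 mV) is retained for comparison; it is
  the weaker rule.

The session engine's default path takes culture events directly (the
spike-level shortcut); the voltage path (waveform synthesis at a target
SNR plus detection) is exercised on shorter segments, since synthesizing
20 minutes of 1024-channel 20 kHz voltage is far outside a desk budget.

## Analysis statistics

* **Clustered binary entropy:** 18 disjoint rectangular clusters of 50
  neighbouring electrodes (a 6 x 3 tiling of 10 x 5 blocks covering 900
  of the 1024 channels; only the cluster counts are canonical, so the
  tiling itself is documented configuration). Per cluster and
  100 ms window, `p` is the fraction of the 50 electrodes with at least
  one spike and the entropy is `H_b(p)`; the statistic is the mean over
  windows and clusters. Normalization divides by the spike count in the
  same windows (zero spikes gives zero by convention). Pre/post
  feedback comparisons use 4 s windows, matching the unpredictable
  stimulus duration.
* **Centre of activity (CA):** count-weighted centroid of electrode
  positions relative to the bottom-left corner. CAs are sampled per 1 s
  bin; the plasticity score is the mean distance of 5-min-window mean
  CAs to the rest recording's centroid, compared between gameplay and
  the rest recording itself. The 1 s sampling bin is a documented choice
  (the aggregation windows, not the sampling bin, are pinned).
* **DCT modes:** orthonormal 2-D type-II DCT of the 32 x 32 activity
  image for frequency pairs (u, v) in 0..2, reported as absolute values
  normalized to mean activity (hence scale-invariant); the four
  first-order asymmetry modes are (0,1), (0,2), (1,0), (2,0), with u the
  vertical frequency.
* **Lagged cross-correlation:** Pearson correlation of 100 ms-binned
  sensory counts against each motor region's counts shifted by one bin;
  a Spearman variant serves the motor-motor synchrony analysis.
* **Exclusive motor events:** per 1 s bin, events with amplitude below
  -5 uV are counted per motor region; a bin is exclusive when exactly
  one region is active; the fraction is over all bins in the span.
* **Session hygiene:** the first 10 s of spiking are excluded from
  electrophysiological statistics (start-up noise), toggleable;
  cross-session summaries exclude |Z| > 3.29 outliers.

## Determinism

A session seed is expanded into named substreams (serve, culture,
feedback, bandit), so toggling one component never shifts another's
draws, and a (config, seed) pair reproduces every log byte for byte. The
acceptance script and all tests draw exclusively through these streams.

## Problem sizes used in the shipped checks

The shipped property suites use 20 seeded 20-minute sessions per learner
condition and 10 per control profile for the learning-direction check; a
30 s, 64-channel voltage fixture at SNR 8 for detector validation; 50
seed pairs of 10-minute stationary rasters for the CA null calibration;
and 20 seeds of 2,000 rounds for the bandit check. These sizes give the
reported contrasts standard errors comfortably inside the asserted
bounds while keeping a full run on one CPU within a coffee break.

## Known limitations

* The learning mechanism needs the action gate and the balanced initial
  coupling; both are modelling commitments, documented above, not
  emergent facts.
* Gain normalization equalizes mean corrected drives but cannot fully
  equalize win probabilities of discrete low-count comparisons; residual
  imbalance shrinks as rates grow.
* The T1/T2 contrast on rally records is undefined for no-feedback
  sessions (one rally); the event-level hit-miss ratio
  (`timepoint_performance()`) is used instead throughout.
* Binary spike logs store sample, channel and amplitude; ground-truth
  labels (spontaneous/evoked/burst) exist only in memory.
* Blinding drops events inside command windows but does not shield the
  noise envelope: a large artifact inflates the slowly settling 1 Hz
  smoother and can suppress detections for a few hundred milliseconds
  after the window. Detector recovery is therefore specified on
  artifact-free input, with blinding checked on its own fixture.
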