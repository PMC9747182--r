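{
  "name": "in_silico_random",
  "baseline_median_hz": 0.25,
  "baseline_sdlog": 0.8,
  "asymmetry": 0,
  "evoked_gain": 0,
  "eta_potentiate": 0,
  "eta_perturb": 0,
  "eta_silent": 0,
  "silent_hit_scale": 0.3,
  "elig_tau_s": 2,
  "w_max": 0.05,
  "burst_rate_hz": 0,
  "burst_duration_s": 0.3,
  "burst_boost_hz": 10
}
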