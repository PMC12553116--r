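# Canonical analysis configuration; keys mirror acwte::default_config().
window:
  length_s: 60
  step_s: 1
bandpass:
  low_hz: 0.05
  high_hz: 0.5
  order: 3
  zero_phase: true
trim_s: 20
acw_kind: acw0
te:
  lags: [1, 2, 3, 4, 5]
  target_history: 1
  source_history: 1
  k_neighbors: 4
  embed_step_s: 10
  theiler_s: 60
n_surrogates: 1000
segments:
  - [20, 246]
  - [267, 525]
  - [545, 794]
  - [815, 897]
window_sweep_s: [60, 120, 180, 240, 300, 360, 420, 480, 540]
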