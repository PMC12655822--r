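seed: 1
axis:
  start: 250.0
  stop: 3000.0
  step: 7.0
preprocess:
  n_segments: 4.0
  degree: 3.0
  n_iterations: 50.0
  floor_zero: yes
  window_points: 5.0
references:
  path: .na
  line_shape: lorentzian
panel:
  noise_sd: 0.015
  baseline_amp: 0.0
population:
  n_per_line: 300.0
  sd: 0.06
  bounds:
  - 0.0
  - 0.79
  noise_sd: 0.015
  baseline_amp: 0.0
  use_spectra: no
unmix:
  mode: nnls
classify:
  train_fraction: 0.7
  n_iterations: 200.0
  n_trees: 100.0
  max_depth: .na
predict:
  n_mixed: 450.0
embed:
  perplexities:
  - 5.0
  - 10.0
  - 20.0
  - 30.0
  - 45.0
  - 60.0
  - 90.0
  - 120.0
  - 150.0
  - 200.0
  - 250.0
  - 300.0
  n_replicates: 5.0
  max_iter: 500.0
  enabled: yes
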