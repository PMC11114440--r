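# Example run configuration for the plihub CLI.
# plihub all --config example-config.yaml --out results/
seed: 1
simulate:
  n_per_group: {control: 31, patient: 21}
  duration_s: 600
  common_source_gain: 1
  noise_gain: 5
analysis:
  filter_order: 4000
  epoch_len_s: 5
  drop_edge_epochs: true
  notch: false
  alpha: 0.05
  q_threshold: 0.05
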