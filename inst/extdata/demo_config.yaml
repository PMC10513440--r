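# Demonstration pipeline configuration (bundled reference, small run)
seed: 42
simulate:
  n_events: 1500
  p_signal: 0.5
  trim_mean: 5.0
  error_rate: 0.0
  clone_size_alpha: 2.5
caller:
  min_germline: 7
detect:
  n_rows: 1000
  spike_fraction: 0.2
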