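# Default analysis parameters (pipeline_config() mirrors these).
filter:
  cutoff_hz: 20
  order: 5
  bidirectional: true
sampling:
  target_fs_hz: 60
validity:
  min_movement_s: 0.5
  max_movement_s: 1.0
reversal_window_s: 0.375
thresholds:
  dur_fracs: [0.1, 0.5]
  peak_frac: 0.5
  peak_sep_s: 0.1
max_reversals_per_direction: 10
task:
  tempo_bpm: 80
  n_cycles: 20
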