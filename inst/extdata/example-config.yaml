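# Example pipeline configuration: overrides merge onto default_config().
wave:
  freq_hz: 2.5
  wavelength_bl: 1.0
model_compare:
  n_noise_reps: 20
  jitter_cv: 0.1
arena:
  stream_speed_label: medium
  centre_band_frac: 0.3333333333333333
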