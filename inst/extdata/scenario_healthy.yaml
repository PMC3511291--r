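name: healthy
population:
  n_units: 100000
  mu_top: 42.0
  sd_top: 19.0
  mu_tcp: 18.0
  sd_tcp: 12.0
  unit_volume: 0.01
settings:
  weight_kg: 24.0
  vt_ml_per_kg: 12.0
  peep_schedule:
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  breaths_per_level: 12.0
  resp_rate: 15.0
  sample_rate: 50.0
  resistance: 0.02
  fio2: 0.5
noise_sd_frac: 0.02
auto_peep: 0.0
seed: 42
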