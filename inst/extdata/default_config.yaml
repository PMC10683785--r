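eeg_sampling_rate: 1000.0
channels:
- Fz
- Cz
- L5
- L6
- L7
- R5
- R6
- R7
pep_latency_range_ms:
- 90.0
- 140.0
pep_duration_ms: 120.0
pep_base_amplitude:
  Fz: 18.0
  Cz: 18.0
  mastoid: 22.0
condition_gain:
  Fz: 1.08
  Cz: 1.045
  mastoid: 1.156
age_gain:
  Fz: 1.0
  Cz: 1.25
  mastoid: 1.2
elder_male_mastoid_gain: 1.5
first_trial_boost: 1.8
amplitude_jitter_sdlog: 0.15
subject_gain_sdlog: 0.3
noise_alpha: 1.0
noise_sd: 10.0
noise_band:
- 1.0
- 45.0
line_noise_amplitude: 5.0
line_noise_freq: 60.0
motion_delay_range_s:
- 0.0
- 0.03
inter_trial_interval_s: 7.0
lead_in_s: 3.0
tail_s: 6.0
accel_noise_sd: 0.01
dropout_events: 40.0
n_per_cell: 10.0
seed: 1
platform:
  sampling_rate: 150.0
  peak_acceleration: 1.962
  target_displacement: 0.2
  target_peak_velocity: 1.0
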