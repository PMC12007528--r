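paradigm:
  preset: paradigm_III
sequence:
  tr_ms: 5.0
  te_ms: 2.4
  fa_deg: 4.0
  rf_phase_increment_deg: 50.0
  n_dummy: 2000.0
phantom:
  preset: brain_slice
  matrix_size: 96.0
response:
  amplitude_pct: 0.05
  onset_ms: 75.0
  duration_ms: 150.0
  shape: boxcar
  active_roi: target_v1
drift:
  rate_pct_per_min: 0.5
  t0_s: 0.0
noise:
  thermal_sigma_pct: 0.1
  physio_preset: default
  seed: 7.0
motion:
  type: none
  step_px: 0.2
  step_deg: 0.05
  seed: 1.0
run:
  n_runs: 3.0
  seed: 1.0
  quantize_16bit: no
  discard_first_run: yes
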