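# Study-protocol defaults: 3D multi-echo UTE stack-of-stars on a 1.5 T
# MR-Linac and the thin-slice GSTF measurement that calibrates it.
# Any entry may be overridden; missing entries fall back to these values.

seq:
  fov_m: 0.5                  # in-plane field of view
  matrix: 332
  spokes_per_partition: 664
  kz_partitions: 103
  tes_ms: [0.176, 1.849, 3.521]
  tr_ms: 8.29                 # sequence repetition time
  tr_motion_ms: 8.61          # repetition time entering the motion interval
  bandwidth_hz_per_pixel: 865
  readout_oversampling: 2
  max_grad_mt_m: 15
  max_slew_mt_m_ms: 65

gstf:
  n_amplitudes: 21            # triangular test pulses
  amp_min_mt_m: 4
  amp_max_mt_m: 15
  slew_mt_m_ms: 65
  slice_offset_mm: 20         # thin slices at +/- 20 mm
  slice_thickness_mm: 3
  window_ms: 30               # readout duration -> 33 Hz resolution
  dwell_us: 0.6               # 1.67 MHz sampling
  n_averages: 100
  n_coils: 8

chain:                        # simulated gradient-chain settling model
  delay_us: 3
  eddy_amp: [0.02, 0.03, 0.01]
  eddy_tau_us: [30, 150, 1500]

filter:                       # GSTF preparation for trajectory correction
  smooth_start_khz: 6
  gauss_sd_khz: 0.6
  tukey_taper: 0.1
  resample_dt_us: 0.1
  pad_ms: 5

phantom:                      # breathing digital phantom
  n: 128
  fov_m: 0.4
  period_s: 4
  peak_displacement_mm: 15
  n_coils: 8

recon:
  n_bins: 5
  overlap: 0.5
  n_iter: 15
  lambda_frac: 0.05
  center_samples: 9
  nav_window: 41
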