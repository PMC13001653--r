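# Example pipeline configuration (reduced-scale synthetic cohort).
# Every stage parameter of the analysis chain is surfaced here.
cohort:
  n_channels: 8
  fs: 100            # Hz; full-scale acquisition geometry would be 5000
  duration_s: 180
  group_hurst:       # target walk-scale Hurst exponent per group
    C: 0.70
    N: 0.55
    O: 0.72
  line_noise: false
  drift: true
  ocular: true
filters:
  band_low: 1        # Hz
  band_high: 45      # Hz (capped at 0.45 * fs)
  drift_cut: 0.2     # Hz
  line_hz: 60
reference:
  method: average    # or rest_approx
ica:
  enabled: true
  template_threshold: 0.7
  kurtosis_threshold: 5
welch:
  window_s: 8        # -> 0.125 Hz resolution
hfd:
  estimator: ghe     # or mfdfa
  q: [1, 2, 3, 4, 5]
  decimate_to_hz: 500
  bands: []          # extra bands beyond the always-included full spectrum
windows:
  length_s: 30
  start_times_s: [0, 30, 60, 90, 120, 150]
stats:
  k: 10
seed: 1
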