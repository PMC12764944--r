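# End-to-end demo: pin-anchored fibrous phantom -> fluence normalization ->
# DoLD/AoLD maps -> whole-image summary and AoLD histogram.
seed: 7
out_dir: demo_out
simulate:
  width: 48
  height: 32
  pattern: pins
  iso: 1.0
  dichroic: 0.8
  noise_sigma: 0.02
  fluence_factors: [1.0, 1.08, 0.95, 1.02]
dichroism:
  min_signal: auto
stats:
  n_bins: 18
  weight_mode: none
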