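# Example run configuration for atrigg::read_run_config() / exec/atrigg.
# Any field omitted falls back to the package default.
sim:
  n_samples: 120
  replicates_per_sample: 5
  noise_sd: 0.001
  scatter_sd: 0.1
  outlier_rate: 0.01
  seed: 11
preprocess: smooth+snv     # one of the nine presets, or a field list
cutoff: 1000               # FTPI cut-off, mg/dL
mccv:
  k_max: 15
  n_repeats: 200
seed: 11
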