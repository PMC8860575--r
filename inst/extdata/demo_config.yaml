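version: 1
seed: 42
out_dir: demo_out
thresholds:
  loc_prob: 0.75
  delta: 40
  padj: 0.05
  fc: 1.5
simulation:
  n_genes: 60
  time_points: ["d-2", "d1", "d3", "d7"]
  n_replicates: 3
  nb_dispersion: 0.05
  labeled_fraction: 0.3
  conversion_rate: 0.02
  depth: 60
slam:
  n_genes: 4
  depth: 120
  min_base_quality: 27
proteomics:
  input_mg: 1.0
modules:
  k: 3
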