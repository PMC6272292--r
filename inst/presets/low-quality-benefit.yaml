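# Low-quality-benefit design: clean training set vs clean + degraded
# (coordinate jitter emulating ~3.5 A resolution, IC50-grade label
# bias/noise), shared clean test set.
name: low-quality-benefit
kind: low_quality
generator:
  n_protein_atoms: 80
  n_ligand_atoms: 22
labels:
  mechanism: nonlinear
  noise_sd: 0.5
  nonlinear_strength: 1.0
n_test: 400
n_clean: 800
n_degraded: 2400
degrade:
  jitter_sd: 0.35
  label_bias_sd: 0.5
  label_noise_sd: 0.5
  fraction: 1.0
models: [mlr_vina, rf_vina]
n_seeds: 10
n_trees: 500
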