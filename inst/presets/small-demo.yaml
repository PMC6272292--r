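# Fast miniature of the volume-trend design, for examples and smoke runs.
name: small-demo
kind: volume
generator:
  n_protein_atoms: 60
  n_ligand_atoms: 18
labels:
  mechanism: nonlinear
  noise_sd: 0.5
  nonlinear_strength: 1.0
n_test: 60
training_sizes: [150, 250]
models: [vina, mlr_vina, rf_vina]
n_seeds: 2
n_trees: 150
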