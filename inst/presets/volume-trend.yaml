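# Data-volume trend: nested training sets from one nonlinear generator.
name: volume-trend
kind: volume
generator:
  n_protein_atoms: 80
  n_ligand_atoms: 22
labels:
  mechanism: nonlinear
  noise_sd: 0.5
  nonlinear_strength: 1.0
n_test: 400
training_sizes: [500, 1000, 2000, 4000]
models: [vina, mlr_vina, rf_vina]
n_seeds: 3
n_trees: 500
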